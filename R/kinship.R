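#' @title Kinship canonicalization
#' @description Canonical ego-relative kinship vocabulary, free-text relation
#'   label parsing, and composition of relations across reporters.
#' @name kinship
NULL

# Canonical vocabulary. `path` encodes the relation as a sequence of pedigree
# steps from ego: P = parent, C = child, S = sibling, M = spouse/partner.
# Non-blood terms (godparent, friend, other) have no path and never compose.
.kin_vocabulary <- function() {
  v <- read.csv(system.file("extdata", "kin_vocabulary.csv", package = "kinnet"),
                stringsAsFactors = FALSE)
  v$offset <- suppressWarnings(as.integer(v$offset))
  v
}

.kin_env <- new.env(parent = emptyenv())

kin_vocab <- function() {
  if (is.null(.kin_env$vocab)) .kin_env$vocab <- .kin_vocabulary()
  .kin_env$vocab
}

#' Generation offset of a canonical kinship term
#'
#' Offsets are relative to the index adult: grandparents +2, parents and
#' aunts/uncles/godparents/parents-in-law +1, ego's own generation 0,
#' children -1, grandchildren -2. Friend/other have no defined offset (NA).
#'
#' @param term character vector of canonical terms.
#' @return integer vector of generation offsets (NA where undefined).
#' @export
kin_offset <- function(term) {
  v <- kin_vocab()
  v$offset[match(term, v$term)]
}

#' Is a canonical term a family relation?
#'
#' @param term character vector of canonical terms.
#' @return logical vector; friend/other are FALSE.
#' @export
kin_is_family <- function(term) {
  v <- kin_vocab()
  out <- v$is_family[match(term, v$term)] == 1
  out[is.na(out)] <- FALSE
  out
}

.kin_terms <- function() kin_vocab()$term

# label keyword dictionary: normalized phrase -> canonical term (+ implied sex)
.label_dictionary <- function() {
  d <- rbind(
    data.frame(phrase = c("mother in law", "father in law", "mum in law", "mom in law",
                          "dad in law"),
               term = "parent_in_law", sex = c("f", "m", "f", "f", "m")),
    data.frame(phrase = c("sister in law", "brother in law"),
               term = "sibling_in_law", sex = c("f", "m")),
    data.frame(phrase = c("son in law", "daughter in law"),
               term = "child_in_law", sex = c("m", "f")),
    data.frame(phrase = c("grandson", "granddaughter", "grandchild"),
               term = "grandchild", sex = c("m", "f", NA)),
    data.frame(phrase = c("grandmother", "grandma", "granny", "grandfather",
                          "grandpa", "gramps", "ah ma", "ah gong", "po po",
                          "gong gong", "nai nai", "ye ye", "grandparent"),
               term = "grandparent",
               sex = c("f", "f", "f", "m", "m", "m", "f", "m", "f", "m", "f", "m", NA)),
    data.frame(phrase = c("granduncle", "grandaunt", "grand uncle", "grand aunt"),
               term = "grandaunt_uncle", sex = c("m", "f", "m", "f")),
    data.frame(phrase = c("godmother", "godfather", "godma", "godpa", "godparent"),
               term = "godparent", sex = c("f", "m", "f", "m", NA)),
    data.frame(phrase = c("mother", "mom", "mum", "mummy", "mommy", "mama"),
               term = "mother", sex = "f"),
    data.frame(phrase = c("father", "dad", "daddy", "papa"),
               term = "father", sex = "m"),
    data.frame(phrase = c("brother", "bro", "sister", "sis", "sibling"),
               term = "sibling", sex = c("m", "m", "f", "f", NA)),
    data.frame(phrase = c("aunt", "auntie", "aunty", "uncle"),
               term = "aunt_uncle", sex = c("f", "f", "f", "m")),
    data.frame(phrase = c("cousin", "cuz"), term = "cousin", sex = NA),
    data.frame(phrase = c("son", "daughter", "child", "kid"),
               term = "child", sex = c("m", "f", NA, NA)),
    data.frame(phrase = c("niece", "nephew"), term = "niece_nephew", sex = c("f", "m")),
    data.frame(phrase = c("husband", "wife", "spouse", "partner", "boyfriend",
                          "girlfriend", "fiance", "fiancee"),
               term = "spouse_partner",
               sex = c("m", "f", NA, NA, "m", "f", "m", "f"))
  )
  d
}

.normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[-_/]", " ", x)
  x <- gsub("[^a-z ]", " ", x)
  gsub("\\s+", " ", trimws(x))
}

# qualifiers carried by survey labels that do not affect kin typing
.kin_qualifiers <- c("oldest", "eldest", "older", "younger", "youngest", "big",
                     "little", "twin", "second", "third", "elder", "my", "step",
                     "half", "maternal", "paternal", "first", "the")

#' Parse a free-text relation label to a canonical kinship term
#'
#' Labels like "mother", "oldest brother" or "auntie AZ" are mapped to the
#' closed canonical vocabulary; qualifiers ("oldest", "maternal") and trailing
#' initials or pseudonym fragments are ignored for kin typing. A label with no
#' recognised kin keyword falls back to the reporter-declared relation class:
#' friend labels (e.g. "gym buddy") become \code{friend}, anything else
#' \code{other}.
#'
#' @param raw_label non-empty character label as given by the reporter.
#' @param relation_class one of "family", "friend", "other".
#' @return a list with elements \code{term} (canonical term) and \code{sex}
#'   ("m", "f" or NA when the label does not imply one).
#' @examples
#' parse_relation_label("auntie AZ", "family")
#' parse_relation_label("gym buddy", "friend")
#' @export
parse_relation_label <- function(raw_label, relation_class = "family") {
  if (length(raw_label) != 1L || is.na(raw_label) || !nzchar(trimws(raw_label)))
    stop("relation label must be a non-empty string", call. = FALSE)
  relation_class <- match.arg(relation_class, c("family", "friend", "other"))
  lab <- .normalize_label(raw_label)
  d <- .label_dictionary()
  # longest phrases first so "mother in law" wins over "mother"
  d <- d[order(-nchar(d$phrase)), ]
  for (i in seq_len(nrow(d))) {
    if (grepl(paste0("\\b", d$phrase[i], "\\b"), lab)) {
      return(list(term = d$term[i], sex = d$sex[i]))
    }
  }
  if (relation_class == "friend") return(list(term = "friend", sex = NA_character_))
  list(term = "other", sex = NA_character_)
}

# ---- path algebra ------------------------------------------------------

.kin_path <- function(term) {
  v <- kin_vocab()
  p <- v$path[match(term, v$term)]
  # sexed parent terms share the "P" path
  p
}

# whole-path -> canonical term; extras cover spouse-of-kin forms
.path_to_term <- function(path) {
  map <- c("P" = "parent", "PP" = "grandparent",
           "PPS" = "grandaunt_uncle", "S" = "sibling", "PS" = "aunt_uncle",
           "PSC" = "cousin", "C" = "child", "SC" = "niece_nephew",
           "CC" = "grandchild", "M" = "spouse_partner", "MP" = "parent_in_law",
           "MS" = "sibling_in_law", "SM" = "sibling_in_law",
           "CM" = "child_in_law", "PSM" = "aunt_uncle", "PPM" = "grandparent")
  ifelse(path == "", "ego", unname(map[path]))
}

# adjacent-pair rewrite rules; each maps a 2-step substring to the possible
# reductions (branching encodes genuine genealogical ambiguity)
.kin_rewrites <- list(
  PC = c("", "S"),   # parent's child: ego or a sibling
  CP = c("", "M"),   # child's parent: ego or ego's spouse
  SS = c("", "S"),   # sibling's sibling
  SP = "P",          # sibling's parent
  CS = "C",          # child's sibling: another child
  PM = "P",          # parent's spouse: a (step)parent
  MM = "",           # spouse's spouse
  MC = "C"           # spouse's child: a (step)child
)

.reduce_paths <- function(path) {
  seen <- character(0)
  frontier <- path
  terminals <- character(0)
  while (length(frontier)) {
    cur <- frontier[1]
    frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    t <- .path_to_term(cur)
    if (!is.na(t)) terminals <- c(terminals, t)
    n <- nchar(cur)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        pair <- substr(cur, i, i + 1)
        reps <- .kin_rewrites[[pair]]
        if (!is.null(reps)) {
          for (r in reps) {
            nxt <- paste0(substr(cur, 1, i - 1), r, substr(cur, i + 2, n))
            if (!(nxt %in% seen)) frontier <- c(frontier, nxt)
          }
        }
      }
    }
  }
  unique(terminals)
}

.specialize_sex <- function(terms, sex) {
  out <- character(0)
  for (t in terms) {
    if (t == "parent") {
      if (identical(sex, "m")) out <- c(out, "father")
      else if (identical(sex, "f")) out <- c(out, "mother")
      else out <- c(out, "father", "mother")
    } else out <- c(out, t)
  }
  unique(out)
}

#' Compose a reporter's relation with a reported relation
#'
#' Given the reporter's canonical relation to the index adult and the relation
#' of a named alter to that reporter, returns every ego-relative canonical
#' relation consistent with the composition. The classic fusion case — the
#' index names a "father", the surveyed mother names her "husband", the
#' surveyed grandmother names her "son" — composes to \code{father} (uniquely
#' for the first two, ambiguously with \code{aunt_uncle} for the third).
#'
#' @param reporter_rel canonical term for the reporter relative to the index
#'   adult ("ego" for the index).
#' @param reported_rel canonical term for the alter relative to the reporter
#'   (as returned by [parse_relation_label()]).
#' @param reported_sex "m", "f" or NA; used to split parent into father/mother.
#' @return a \code{candidate_set}: list with \code{candidates} (character),
#'   \code{ambiguous} (flag), \code{resolution_source} ("unique" or
#'   "unresolved"). Compositions outside the vocabulary yield
#'   \code{candidates = "other"}, never an error.
#' @examples
#' compose_relations("mother", "spouse_partner", "m")   # -> father
#' compose_relations("grandparent", "child", "m")       # -> father or uncle
#' @export
compose_relations <- function(reporter_rel, reported_rel, reported_sex = NA) {
  stopifnot(length(reporter_rel) == 1L, length(reported_rel) == 1L)
  mk <- function(cands, src) {
    structure(list(candidates = cands, ambiguous = length(cands) > 1L,
                   resolution_source = src), class = "candidate_set")
  }
  if (!(reporter_rel %in% .kin_terms()))
    return(mk("other", "unresolved"))
  if (reported_rel %in% c("friend", "other"))
    return(mk(reported_rel, "unique"))
  if (reporter_rel == "ego") {
    cands <- .specialize_sex(
      if (reported_rel == "parent") "parent" else reported_rel, reported_sex)
    return(mk(cands, if (length(cands) == 1L) "unique" else "unresolved"))
  }
  if (reporter_rel %in% c("friend", "other", "godparent") ||
      reported_rel == "godparent")
    return(mk("other", "unresolved"))
  p1 <- .kin_path(reporter_rel)
  p2 <- if (reported_rel == "parent") "P" else .kin_path(reported_rel)
  if (is.na(p1) || is.na(p2)) return(mk("other", "unresolved"))
  terms <- .reduce_paths(paste0(p1, p2))
  terms <- .specialize_sex(terms, reported_sex)
  if (!length(terms)) return(mk("other", "unresolved"))
  mk(terms, if (length(terms) == 1L) "unique" else "unresolved")
}

#' Resolve an ambiguous candidate set
#'
#' Resolution order mirrors the study workflow (the research team contacted
#' participants to clarify ambiguous nodes): (1) a manual override row for
#' this reporter/label, (2) a cross-reporter match — a uniquely-resolved node
#' already in the registry whose relation is among the candidates and whose
#' sex agrees and age is within \code{age_tol} years (nearest age wins; a tie
#' leaves the node unresolved), (3) otherwise the set stays unresolved and
#' the node is excluded from generational classification (treated as
#' \code{other}).
#'
#' @param cands a \code{candidate_set} from [compose_relations()].
#' @param alter_sex,alter_age sex ("m"/"f"/NA) and approximate age in years
#'   (NA allowed) of the reported alter.
#' @param registry_context data frame of already-resolved nodes with columns
#'   \code{term}, \code{sex}, \code{age} (uniquely-resolved nodes only).
#' @param override optional single canonical term from the manual-override
#'   table; takes precedence over matching.
#' @param age_tol matching tolerance in years (default 5).
#' @return a \code{candidate_set} with one candidate and
#'   \code{resolution_source} in \{unique, manual_override,
#'   cross_reporter_match, unresolved\}; unresolved sets keep candidates but
#'   classify as "other" downstream.
#' @export
resolve_candidates <- function(cands, alter_sex = NA, alter_age = NA,
                               registry_context = NULL, override = NULL,
                               age_tol = 5) {
  stopifnot(inherits(cands, "candidate_set"), length(cands$candidates) >= 1L)
  if (!is.null(override) && !is.na(override) && nzchar(override)) {
    if (!(override %in% .kin_terms()))
      stop("override label '", override, "' is not in the canonical vocabulary",
           call. = FALSE)
    return(structure(list(candidates = override, ambiguous = FALSE,
                          resolution_source = "manual_override"),
                     class = "candidate_set"))
  }
  if (!cands$ambiguous) {
    cands$resolution_source <- "unique"
    return(cands)
  }
  if (!is.null(registry_context) && nrow(registry_context)) {
    hit <- registry_context[registry_context$term %in% cands$candidates, ,
                            drop = FALSE]
    if (!is.na(alter_sex) && nrow(hit))
      hit <- hit[is.na(hit$sex) | hit$sex == alter_sex, , drop = FALSE]
    if (!is.na(alter_age) && nrow(hit)) {
      d <- abs(hit$age - alter_age)
      d[is.na(d)] <- age_tol  # unknown registry age: admissible but worst-ranked
      hit <- hit[d <= age_tol, , drop = FALSE]
      d <- d[d <= age_tol]
      if (nrow(hit) > 1L) {
        best <- which(d == min(d))
        hit <- if (length(best) == 1L) hit[best, , drop = FALSE] else hit[0, , drop = FALSE]
      }
    }
    if (nrow(hit) == 1L) {
      return(structure(list(candidates = hit$term[1], ambiguous = FALSE,
                            resolution_source = "cross_reporter_match"),
                       class = "candidate_set"))
    }
  }
  cands$resolution_source <- "unresolved"
  cands
}
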