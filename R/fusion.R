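#' @title Household network fusion
#' @description Merge the egocentric reports of all surveyed members of a
#'   household into one fused network: deduplicate nodes via canonical
#'   kinship relations, consolidate dyadic ratings by averaging across
#'   reporters, classify every tie, and expand to directed records.
#' @name network_fusion
NULL

# terms occupying a unique slot in a household: merge on term alone
.unique_slot_terms <- c("ego", "father", "mother")

.norm_friend_label <- function(x) gsub("\\s+", " ", tolower(trimws(x)))

#' Build the fused node registry for one household
#'
#' Surveyed participants seed the registry (self-reported sex, age, health and
#' effort take precedence over perceptions). Every alter report is parsed,
#' composed with the reporter's own relation to the index adult, and resolved
#' (manual override, then cross-reporter/participant matching by sex and
#' nearest age within \code{age_tol}). Alters resolving to the same kin slot
#' merge into one node; friends merge only on exact normalized label match;
#' unresolved alters are retained as relation "other" and never merged.
#' Perceived attributes of merged nodes are averaged across reporters.
#'
#' @param survey a \code{household_survey}.
#' @param age_tol cross-reporter age tolerance in years (default 5).
#' @return a \code{node_registry}: data frame with columns node_id, term, sex,
#'   age, health, effort, surveyed, participant_id, reporter_count,
#'   resolution, plus attributes \code{ref_map} (per-reporter label -> node_id
#'   lookup) and \code{couples} (explicit spouse links from labels).
#' @export
deduplicate_nodes <- function(survey, age_tol = 5) {
  p <- survey$participants
  ov <- survey$overrides
  nodes <- data.frame(
    node_id = paste0(survey$household_id, ":", p$participant_id),
    term = NA_character_, sex = p$sex, age = as.numeric(p$age),
    health = as.numeric(p$self_health), effort = as.numeric(p$self_effort),
    surveyed = TRUE, participant_id = p$participant_id,
    reporter_count = 0L, resolution = "surveyed",
    label = NA_character_,
    stringsAsFactors = FALSE)
  # participants' canonical relation to the index adult
  for (i in seq_len(nrow(p))) {
    if (p$is_index[i] == 1) nodes$term[i] <- "ego"
    else {
      pr <- parse_relation_label(p$relation_to_index[i], "family")
      nodes$term[i] <- pr$term
    }
  }
  dup <- nodes$term[duplicated(nodes$term) & nodes$term %in% .unique_slot_terms]
  if (length(dup))
    stop("integrity error: two surveyed participants occupy kin slot '",
         dup[1], "'", call. = FALSE)
  # accumulators for perceived attributes (participants keep self-reports)
  acc <- list()
  ref_map <- list()       # ref_map[[reporter_id]][[label]] <- node_id
  couples <- list()       # explicit spouse links detected from labels
  node_reporters <- list()  # reporters already merged into each node
  a <- survey$alters
  if (nrow(a)) {
    reporter_term <- nodes$term[match(a$reporter_id, nodes$participant_id)]
    parsed <- lapply(seq_len(nrow(a)), function(i)
      parse_relation_label(a$alter_label[i], a$relation_class[i]))
    comp <- lapply(seq_len(nrow(a)), function(i) {
      sx <- if (!is.na(a$sex[i]) && nzchar(a$sex[i])) a$sex[i] else parsed[[i]]$sex
      compose_relations(reporter_term[i], parsed[[i]]$term, sx)
    })
    # two passes: unique compositions first so they can anchor cross-matches
    order_idx <- order(vapply(comp, function(cs) cs$ambiguous, logical(1)))
    for (i in order_idx) {
      rep_id <- a$reporter_id[i]
      lab <- a$alter_label[i]
      sx <- if (!is.na(a$sex[i]) && nzchar(a$sex[i])) a$sex[i] else parsed[[i]]$sex
      age_i <- suppressWarnings(as.numeric(a$age_approx[i]))
      key <- ov[ov$reporter_id == rep_id & ov$alter_label == lab, , drop = FALSE]
      if (nrow(key) > 1)
        stop("configuration error: conflicting overrides for reporter ",
             rep_id, " label '", lab, "'", call. = FALSE)
      override <- if (nrow(key) == 1) key$resolved_label[1] else NULL
      ctx <- nodes[nodes$resolution %in%
                     c("surveyed", "unique", "manual_override",
                       "cross_reporter_match") & kin_is_family(nodes$term),
                   c("term", "sex", "age"), drop = FALSE]
      res <- resolve_candidates(comp[[i]], alter_sex = sx, alter_age = age_i,
                                registry_context = ctx, override = override,
                                age_tol = age_tol)
      term <- if (res$resolution_source == "unresolved") "other"
              else res$candidates[1]
      # find merge target; a reporter's own alters never merge together
      seen_rep <- function(idx) {
        rep_id %in% node_reporters[[nodes$node_id[idx]]]
      }
      target <- NA_integer_
      if (term == "friend") {
        hit <- which(nodes$term == "friend" &
                       .norm_friend_label(nodes$label) == .norm_friend_label(lab))
        hit <- hit[!vapply(hit, seen_rep, logical(1))]
        if (length(hit)) target <- hit[1]
      } else if (term %in% .unique_slot_terms) {
        hit <- which(nodes$term == term)
        if (length(hit)) target <- hit[1]
      } else if (kin_is_family(term) && term != "other") {
        hit <- which(nodes$term == term &
                       (is.na(nodes$sex) | is.na(sx) | nodes$sex == sx))
        hit <- hit[!vapply(hit, seen_rep, logical(1))]
        if (length(hit) && !is.na(age_i)) {
          d <- abs(nodes$age[hit] - age_i)
          d[is.na(d)] <- age_tol
          hit <- hit[d <= age_tol][order(d[d <= age_tol])]
        }
        if (length(hit)) target <- hit[1]
      }
      if (is.na(target)) {
        nid <- paste0(survey$household_id, ":", rep_id, ":", make.names(lab))
        nodes <- rbind(nodes, data.frame(
          node_id = nid, term = term, sex = sx,
          age = age_i, health = NA_real_, effort = NA_real_,
          surveyed = FALSE, participant_id = NA_character_,
          reporter_count = 0L, resolution = res$resolution_source,
          label = lab,
          stringsAsFactors = FALSE))
        target <- nrow(nodes)
      }
      nid <- nodes$node_id[target]
      node_reporters[[nid]] <- c(node_reporters[[nid]], rep_id)
      acc[[nid]] <- rbind(acc[[nid]],
                          data.frame(health = a$perceived_health[i],
                                     effort = a$perceived_effort[i],
                                     age = age_i))
      nodes$reporter_count[target] <- nodes$reporter_count[target] + 1L
      ref_map[[rep_id]] <- c(ref_map[[rep_id]],
                             stats::setNames(nid, lab))
      if (parsed[[i]]$term == "spouse_partner") {
        rep_nid <- nodes$node_id[match(rep_id, nodes$participant_id)]
        couples[[length(couples) + 1]] <- sort(c(rep_nid, nid))
      }
    }
  }
  # fold accumulated perceptions into non-surveyed nodes
  for (nid in names(acc)) {
    j <- match(nid, nodes$node_id)
    if (!nodes$surveyed[j]) {
      nodes$health[j] <- if (all(is.na(acc[[nid]]$health))) NA_real_
                         else mean(acc[[nid]]$health, na.rm = TRUE)
      nodes$effort[j] <- if (all(is.na(acc[[nid]]$effort))) NA_real_
                         else mean(acc[[nid]]$effort, na.rm = TRUE)
      nodes$age[j] <- if (all(is.na(acc[[nid]]$age))) NA_real_
                      else mean(acc[[nid]]$age, na.rm = TRUE)
    }
  }
  # participants can also reference each other by id in ratings
  for (pid in p$participant_id)
    for (q in p$participant_id)
      ref_map[[pid]][q] <- nodes$node_id[match(q, nodes$participant_id)]
  rownames(nodes) <- NULL
  structure(nodes, ref_map = ref_map, couples = unique(couples),
            household_id = survey$household_id,
            class = c("node_registry", "data.frame"))
}

.lookup_ref <- function(ref_map, reporter_id, ref) {
  m <- ref_map[[reporter_id]]
  if (!is.null(m) && ref %in% names(m)) return(unname(m[ref]))
  NA_character_
}

#' Consolidate dyadic ratings into a fused edgelist
#'
#' Each reported dyad maps to one unordered node pair; where several
#' reporters rated the same pair, their ratings are averaged component-wise.
#' The two importance ratings stay directional and are aligned to the stored
#' pair order before averaging.
#'
#' @param survey a \code{household_survey}.
#' @param registry output of [deduplicate_nodes()].
#' @return data frame of fused edges (class \code{fused_edgelist}): a, b
#'   (node ids, a < b), the five averaged ratings, reporter_count.
#' @export
consolidate_edges <- function(survey, registry) {
  r <- survey$ratings
  ref_map <- attr(registry, "ref_map")
  if (!nrow(r)) {
    out <- data.frame(a = character(0), b = character(0),
                      interact_freq = numeric(0), closeness = numeric(0),
                      eat_freq = numeric(0), importance_ab = numeric(0),
                      importance_ba = numeric(0), reporter_count = integer(0))
    class(out) <- c("fused_edgelist", "data.frame")
    return(out)
  }
  a_id <- b_id <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    a_id[i] <- .lookup_ref(ref_map, r$reporter_id[i], r$person_a[i])
    b_id[i] <- .lookup_ref(ref_map, r$reporter_id[i], r$person_b[i])
    if (is.na(a_id[i]) || is.na(b_id[i]))
      stop("referential error: rating row ", i, " references person not in ",
           "registry ('", r$person_a[i], "'/'", r$person_b[i], "')",
           call. = FALSE)
  }
  flip <- a_id > b_id
  key_a <- ifelse(flip, b_id, a_id)
  key_b <- ifelse(flip, a_id, b_id)
  imp_ab <- ifelse(flip, r$importance_b_in_a, r$importance_a_in_b)
  imp_ba <- ifelse(flip, r$importance_a_in_b, r$importance_b_in_a)
  key <- paste(key_a, key_b, sep = "\r")
  agg <- function(x) tapply(x, key, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  ks <- sort(unique(key))
  out <- data.frame(
    a = sub("\r.*", "", ks), b = sub(".*\r", "", ks),
    interact_freq = as.numeric(agg(r$interact_freq)[ks]),
    closeness = as.numeric(agg(r$closeness)[ks]),
    eat_freq = as.numeric(agg(r$eat_freq)[ks]),
    importance_ab = as.numeric(agg(imp_ab)[ks]),
    importance_ba = as.numeric(agg(imp_ba)[ks]),
    reporter_count = as.integer(tapply(r$reporter_id, key,
                                       function(v) length(unique(v)))[ks]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fused_edgelist", "data.frame")
  out
}

# couple table over canonical terms (beyond explicit spouse labels)
.couple_pairs <- list(c("father", "mother"), c("ego", "spouse_partner"),
                      c("sibling", "sibling_in_law"),
                      c("child", "child_in_law"))

#' Classify a fused tie
#'
#' Precedence: spouse/partner ties win (detected from explicit spouse labels
#' or from canonical couple slots such as father+mother); then any tie with a
#' non-family endpoint is a friend tie; remaining family ties are
#' intergenerational when the generation offsets differ and intragenerational
#' when equal. Ties with an unresolved endpoint are "other".
#'
#' @param a_term,b_term canonical terms of the two endpoints.
#' @param couple logical: the endpoints are an explicitly-labelled couple.
#' @return character category: one of intergenerational, intragenerational,
#'   spouse_partner, friend, other.
#' @export
classify_edge <- function(a_term, b_term, couple = FALSE) {
  if (is.na(a_term) || is.na(b_term) ||
      a_term == "other" || b_term == "other") return("other")
  pair <- sort(c(a_term, b_term))
  if (couple) return("spouse_partner")
  for (cp in .couple_pairs)
    if (identical(pair, sort(cp))) return("spouse_partner")
  if (!kin_is_family(a_term) || !kin_is_family(b_term)) return("friend")
  da <- kin_offset(a_term); db <- kin_offset(b_term)
  if (is.na(da) || is.na(db)) return("other")
  if (abs(da - db) >= 1) "intergenerational" else "intragenerational"
}

#' Fuse one household survey into a network
#'
#' Runs node deduplication, edge consolidation and tie classification.
#'
#' @param survey a \code{household_survey}.
#' @param age_tol cross-reporter age matching tolerance (years).
#' @return a \code{household_network}: list with \code{registry},
#'   \code{edges} (with \code{category} column) and \code{household_id}.
#' @export
fuse_household <- function(survey, age_tol = 5) {
  registry <- deduplicate_nodes(survey, age_tol = age_tol)
  edges <- consolidate_edges(survey, registry)
  couples <- attr(registry, "couples")
  is_couple <- function(a, b) {
    any(vapply(couples, function(cp) identical(sort(c(a, b)), cp), logical(1)))
  }
  if (nrow(edges)) {
    edges$category <- vapply(seq_len(nrow(edges)), function(i) {
      ta <- registry$term[match(edges$a[i], registry$node_id)]
      tb <- registry$term[match(edges$b[i], registry$node_id)]
      classify_edge(ta, tb, couple = is_couple(edges$a[i], edges$b[i]))
    }, character(1))
  } else edges$category <- character(0)
  structure(list(household_id = survey$household_id, registry = registry,
                 edges = edges), class = "household_network")
}

#' @export
print.household_network <- function(x, ...) {
  cat("household_network", x$household_id, "-", nrow(x$registry), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) print(table(x$edges$category))
  invisible(x)
}

#' Expand a fused network to directed dyad records
#'
#' Every fused tie yields exactly two directed records: a as source with
#' outcome \code{importance_ab} (a's importance in b's health) and b as
#' source with \code{importance_ba}. Source and target covariates (age, sex,
#' health, effort, surveyed flag) are attached; for intergenerational ties
#' the direction subtype records whether the target sits in an older or
#' younger generation than the source. Records with missing covariates are
#' kept; models handle exclusion.
#'
#' @param network a \code{household_network}.
#' @return data frame of directed dyad records.
#' @export
build_directed_records <- function(network) {
  e <- network$edges
  reg <- network$registry
  if (!nrow(e)) return(data.frame())
  one_dir <- function(src, tgt, outcome) {
    si <- match(src, reg$node_id); ti <- match(tgt, reg$node_id)
    doff <- kin_offset(reg$term[ti]) - kin_offset(reg$term[si])
    subtype <- ifelse(e$category != "intergenerational", "same",
                      ifelse(doff > 0, "target_older", "target_younger"))
    data.frame(
      household_id = network$household_id,
      source_node = src, target_node = tgt,
      outcome = outcome,
      interact_freq = e$interact_freq, closeness = e$closeness,
      eat_freq = e$eat_freq,
      category = e$category, direction_subtype = subtype,
      source_age = reg$age[si], source_sex = reg$sex[si],
      source_health = reg$health[si], source_effort = reg$effort[si],
      source_surveyed = reg$surveyed[si],
      source_participant = reg$participant_id[si],
      target_age = reg$age[ti], target_sex = reg$sex[ti],
      target_health = reg$health[ti], target_effort = reg$effort[ti],
      target_surveyed = reg$surveyed[ti],
      stringsAsFactors = FALSE)
  }
  out <- rbind(one_dir(e$a, e$b, e$importance_ab),
               one_dir(e$b, e$a, e$importance_ba))
  rownames(out) <- NULL
  out
}

#' Export a fused network as an igraph object
#'
#' Node attributes: canonical relation, sex, age, health, effort, surveyed;
#' edge attributes: the five averaged ratings, category, reporter_count.
#'
#' @param network a \code{household_network}.
#' @return an \code{igraph} graph.
#' @export
as_igraph <- function(network) {
  reg <- network$registry
  verts <- data.frame(name = reg$node_id, relation = reg$term, sex = reg$sex,
                      age = reg$age, health = reg$health, effort = reg$effort,
                      surveyed = reg$surveyed, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = verts)
}

#' Write a fused network to GraphML
#'
#' @param network a \code{household_network}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  # GraphML cannot carry NA logical/numeric attributes cleanly
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
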