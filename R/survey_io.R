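#' @title Survey ingestion and validation
#' @description Read the three survey tables (participants, alters, dyadic
#'   ratings) plus an optional manual-override table, validate them, and
#'   split them into per-household survey objects.
#' @name survey_io
NULL

.participant_cols <- c("participant_id", "household_id", "is_index",
                       "relation_to_index", "age", "sex", "race", "income",
                       "housing", "bmi", "marital_status", "self_health",
                       "self_effort", paste0("hi", 1:4), paste0("vc", 1:4),
                       "diet_veg", "diet_fruit", "diet_snacks", "diet_fastfood")
.alter_cols <- c("reporter_id", "alter_label", "relation_class", "sex",
                 "age_approx", "perceived_health", "perceived_effort")
.rating_cols <- c("reporter_id", "person_a", "person_b", "interact_freq",
                  "closeness", "eat_freq", "importance_a_in_b",
                  "importance_b_in_a")
.override_cols <- c("household_id", "reporter_id", "alter_label",
                    "resolved_label")

#' Seven-level diet frequency labels
#'
#' Levels 0--6: none; 1--3x/week; 4--6x/week; 1x/day; 2x/day; 3x/day;
#' 4+x/day. This is the minimal labelling consistent with all four
#' dichotomization thresholds used downstream.
#' @return character vector of 7 labels (level = position - 1).
#' @export
diet_levels <- function() {
  c("none", "1-3x/week", "4-6x/week", "1x/day", "2x/day", "3x/day", "4+x/day")
}

#' Age banding used for reporting and modelling
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels "19-39", "40-59", "60+".
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 39, 59, Inf), labels = c("19-39", "40-59", "60+"))
}

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.check_range <- function(x, lo, hi, what, allow_na = FALSE) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (!allow_na) bad <- union(bad, which(is.na(x)))
  if (length(bad))
    stop("validation error: ", what, " out of [", lo, ",", hi, "] at row ",
         bad[1], call. = FALSE)
}

.validate_participants <- function(p) {
  .check_cols(p, .participant_cols, "participants")
  .check_range(p$self_health, 1, 10, "self_health", allow_na = TRUE)
  .check_range(p$self_effort, 1, 10, "self_effort", allow_na = TRUE)
  for (col in c(paste0("hi", 1:4), paste0("vc", 1:4)))
    .check_range(p[[col]], 1, 9, col, allow_na = TRUE)
  for (col in c("diet_veg", "diet_fruit", "diet_snacks", "diet_fastfood"))
    .check_range(p[[col]], 0, 6, col, allow_na = TRUE)
  if (anyDuplicated(p$participant_id))
    stop("validation error: duplicated participant_id", call. = FALSE)
  n_index <- tapply(p$is_index, p$household_id, sum)
  if (any(n_index != 1))
    stop("validation error: household(s) without exactly one index adult: ",
         paste(names(n_index)[n_index != 1], collapse = ", "), call. = FALSE)
  n_other <- tapply(1 - p$is_index, p$household_id, sum)
  if (any(n_other < 1 | n_other > 3))
    stop("validation error: households must have 1-3 co-surveyed members: ",
         paste(names(n_other)[n_other < 1 | n_other > 3], collapse = ", "),
         call. = FALSE)
  invisible(p)
}

.validate_alters <- function(a, participants) {
  .check_cols(a, .alter_cols, "alters")
  orphan <- setdiff(a$reporter_id, participants$participant_id)
  if (length(orphan))
    stop("referential error: alter reporter_id not in participants: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  .check_range(a$perceived_health, 1, 10, "perceived_health", allow_na = TRUE)
  .check_range(a$perceived_effort, 1, 10, "perceived_effort", allow_na = TRUE)
  n <- table(a$reporter_id)
  if (any(n < 2 | n > 10))
    stop("validation error: reporters must name 2-10 alters: ",
         paste(names(n)[n < 2 | n > 10], collapse = ", "), call. = FALSE)
  invisible(a)
}

.validate_ratings <- function(r, participants, alters) {
  .check_cols(r, .rating_cols, "ratings")
  orphan <- setdiff(r$reporter_id, participants$participant_id)
  if (length(orphan))
    stop("referential error: rating reporter_id not in participants: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  for (col in c("interact_freq", "closeness", "eat_freq", "importance_a_in_b",
                "importance_b_in_a"))
    .check_range(r[[col]], 0, 9, col, allow_na = TRUE)
  same <- which(r$person_a == r$person_b)
  if (length(same))
    stop("validation error: person_a == person_b at row ", same[1],
         call. = FALSE)
  # every rated person must be the reporter, another participant of the same
  # household, or an alter named by the same reporter
  for (i in seq_len(nrow(r))) {
    rep_id <- r$reporter_id[i]
    hh <- participants$household_id[match(rep_id, participants$participant_id)]
    known <- c(participants$participant_id[participants$household_id == hh],
               alters$alter_label[alters$reporter_id == rep_id])
    bad <- setdiff(c(r$person_a[i], r$person_b[i]), known)
    if (length(bad))
      stop("referential error: rating row ", i, " references unknown person '",
           bad[1], "' for reporter ", rep_id, call. = FALSE)
  }
  invisible(r)
}

#' Read and validate household survey tables
#'
#' Reads the three survey CSV exports (and an optional manual-override table
#' for ambiguous kin labels), enforces the data-model invariants, and returns
#' one \code{household_survey} object per household. Any malformed cell
#' produces a located error; nothing is silently coerced.
#'
#' @param participants_path,alters_path,ratings_path CSV paths with the
#'   documented column sets (see [survey_column_dictionary()]).
#' @param overrides_path optional CSV with columns household_id, reporter_id,
#'   alter_label, resolved_label.
#' @return named list of \code{household_survey} objects (one per household),
#'   each a list with elements \code{household_id}, \code{participants},
#'   \code{alters}, \code{ratings}, \code{overrides}.
#' @export
read_household_surveys <- function(participants_path, alters_path,
                                   ratings_path, overrides_path = NULL) {
  p <- utils::read.csv(participants_path, stringsAsFactors = FALSE)
  a <- utils::read.csv(alters_path, stringsAsFactors = FALSE)
  r <- utils::read.csv(ratings_path, stringsAsFactors = FALSE)
  o <- if (!is.null(overrides_path) && file.exists(overrides_path))
    utils::read.csv(overrides_path, stringsAsFactors = FALSE)
  else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 4)), .override_cols)
  as_household_surveys(p, a, r, o)
}

#' Assemble household surveys from in-memory tables
#'
#' Same contract as [read_household_surveys()] but starting from data frames
#' (as produced by [generate_cohort()]).
#'
#' @param participants,alters,ratings,overrides data frames.
#' @return named list of \code{household_survey} objects.
#' @export
as_household_surveys <- function(participants, alters, ratings,
                                 overrides = NULL) {
  if (is.null(overrides))
    overrides <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 4)),
                                 .override_cols)
  .check_cols(overrides, .override_cols, "overrides")
  .validate_participants(participants)
  .validate_alters(alters, participants)
  .validate_ratings(ratings, participants, alters)
  hh <- sort(unique(participants$household_id))
  out <- lapply(hh, function(h) {
    pid <- participants$participant_id[participants$household_id == h]
    structure(list(
      household_id = h,
      participants = participants[participants$household_id == h, , drop = FALSE],
      alters = alters[alters$reporter_id %in% pid, , drop = FALSE],
      ratings = ratings[ratings$reporter_id %in% pid, , drop = FALSE],
      overrides = overrides[overrides$household_id == h, , drop = FALSE]
    ), class = "household_survey")
  })
  stats::setNames(out, as.character(hh))
}

#' @export
print.household_survey <- function(x, ...) {
  cat("household_survey", x$household_id, "-", nrow(x$participants),
      "participants,", nrow(x$alters), "alter reports,", nrow(x$ratings),
      "rated dyads\n")
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' @param cohort list with elements \code{participants}, \code{alters},
#'   \code{ratings} and optionally \code{overrides} (data frames).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             alters = file.path(dir, "alters.csv"),
             ratings = file.path(dir, "ratings.csv"),
             overrides = file.path(dir, "overrides.csv"))
  utils::write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  utils::write.csv(cohort$alters, paths["alters"], row.names = FALSE)
  utils::write.csv(cohort$ratings, paths["ratings"], row.names = FALSE)
  if (!is.null(cohort$overrides))
    utils::write.csv(cohort$overrides, paths["overrides"], row.names = FALSE)
  invisible(paths)
}

#' Cohort descriptive summary
#'
#' Tabulates surveyed participants and (separately) the non-surveyed people
#' they named: counts and percentages by age band, sex and race, plus
#' means/sds of self-rated health, effort, and the individualism/collectivism
#' scale scores.
#'
#' @param surveys list of \code{household_survey} objects.
#' @return data frame with columns \code{group} ("participants"/"alters"),
#'   \code{measure}, \code{level}, \code{n}, \code{pct}, \code{mean},
#'   \code{sd}.
#' @export
summarize_cohort <- function(surveys) {
  stopifnot(length(surveys) >= 1)
  p <- do.call(rbind, lapply(surveys, `[[`, "participants"))
  a <- do.call(rbind, lapply(surveys, `[[`, "alters"))
  rows <- list()
  add_cat <- function(group, measure, x) {
    x <- x[!is.na(x)]
    tb <- table(x)
    for (lv in names(tb)) {
      rows[[length(rows) + 1]] <<- data.frame(
        group = group, measure = measure, level = lv,
        n = as.integer(tb[[lv]]), pct = 100 * tb[[lv]] / length(x),
        mean = NA_real_, sd = NA_real_)
    }
  }
  add_num <- function(group, measure, x) {
    x <- x[!is.na(x)]
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, measure = measure, level = NA_character_,
      n = length(x), pct = NA_real_,
      mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  add_cat("participants", "age_band", age_band(p$age))
  add_cat("participants", "sex", p$sex)
  add_cat("participants", "race", p$race)
  add_num("participants", "self_health", p$self_health)
  add_num("participants", "self_effort", p$self_effort)
  add_num("participants", "hi_score", rowSums(p[paste0("hi", 1:4)]))
  add_num("participants", "vc_score", rowSums(p[paste0("vc", 1:4)]))
  if (nrow(a)) {
    add_cat("alters", "age_band", age_band(a$age_approx))
    add_cat("alters", "sex", a$sex)
    add_num("alters", "perceived_health", a$perceived_health)
    add_num("alters", "perceived_effort", a$perceived_effort)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column dictionary for the three survey tables
#'
#' @return named list of character vectors (required columns per table).
#' @export
survey_column_dictionary <- function() {
  list(participants = .participant_cols, alters = .alter_cols,
       ratings = .rating_cols, overrides = .override_cols)
}
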