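#' @title Cultural-orientation scales and diet dichotomization
#' @description Score the 4-item horizontal-individualism and
#'   vertical-collectivism scales, split them at the sample median, and
#'   dichotomize the four diet-frequency items against their guideline
#'   thresholds.
#' @name scales
NULL

#' Sum a 4-item 9-point scale
#'
#' @param items numeric vector of exactly 4 item responses, each in 1--9.
#' @return integer score in 4--36.
#' @export
score_scale <- function(items) {
  if (length(items) != 4L)
    stop("validation error: scale needs exactly 4 items", call. = FALSE)
  if (anyNA(items) || any(items < 1 | items > 9))
    stop("validation error: scale items must be in [1,9]", call. = FALSE)
  as.integer(sum(items))
}

#' Median split of scale scores
#'
#' Dichotomizes scores into above-median ("high") versus at-or-below-median,
#' with the median computed on the analysis sample. Ties at the median go to
#' the not-high group (strict greater-than rule).
#'
#' @param scores numeric vector (length >= 2); NAs propagate.
#' @return list with \code{median}, \code{high} (logical vector) and
#'   \code{degenerate} (TRUE when one group is empty, e.g. all-equal scores;
#'   also warned about).
#' @export
median_split <- function(scores) {
  ok <- scores[!is.na(scores)]
  if (length(ok) < 2)
    stop("sample-size error: median split needs >= 2 non-missing scores",
         call. = FALSE)
  med <- stats::median(ok)
  high <- scores > med
  degenerate <- all(high[!is.na(high)]) || !any(high[!is.na(high)])
  if (degenerate)
    warning("median split is degenerate: one group is empty", call. = FALSE)
  list(median = med, high = high, degenerate = degenerate)
}

#' Dichotomize the four diet-frequency items
#'
#' Levels are the seven ordinal frequencies of [diet_levels()] (0 = none ...
#' 6 = 4+ times/day). Thresholds: vegetables meet guidelines at >= 2x/day
#' (level >= 4); fruit at >= 1x/day (level >= 3); fast food flagged when none
#' at all (level == 0); snacks flagged "low" at <= 3x/week (level <= 1).
#'
#' @param veg,fruit,snacks,fastfood integer levels in 0--6 (vectorized).
#' @return data frame with logical columns veg_meets, fruit_meets,
#'   fastfood_none, snacks_low.
#' @export
dichotomize_diet <- function(veg, fruit, snacks, fastfood) {
  chk <- function(x, nm) {
    if (any(!is.na(x) & (x < 0 | x > 6)))
      stop("validation error: ", nm, " level out of [0,6]", call. = FALSE)
    x
  }
  data.frame(
    veg_meets = chk(veg, "veg") >= 4,
    fruit_meets = chk(fruit, "fruit") >= 3,
    fastfood_none = chk(fastfood, "fastfood") == 0,
    snacks_low = chk(snacks, "snacks") <= 1)
}

#' Cronbach's alpha
#'
#' Internal-consistency diagnostic for the 4-item scales.
#'
#' @param items matrix or data frame, one column per item.
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  vi <- sum(apply(items, 2, stats::var))
  vt <- stats::var(rowSums(items))
  k / (k - 1) * (1 - vi / vt)
}

#' Code scales and diet flags for all participants
#'
#' Computes HI/VC scores, sample-median splits, diet flags and scale
#' reliability for the pooled participants of a cohort.
#'
#' @param surveys list of \code{household_survey} objects.
#' @return list with \code{coded} (per-participant data frame keyed by
#'   participant_id), \code{hi_median}, \code{vc_median}, \code{alpha_hi},
#'   \code{alpha_vc}.
#' @export
code_participants <- function(surveys) {
  p <- do.call(rbind, lapply(surveys, `[[`, "participants"))
  hi <- rowSums(p[paste0("hi", 1:4)])
  vc <- rowSums(p[paste0("vc", 1:4)])
  hi_split <- median_split(hi)
  vc_split <- median_split(vc)
  flags <- dichotomize_diet(p$diet_veg, p$diet_fruit, p$diet_snacks,
                            p$diet_fastfood)
  coded <- cbind(
    data.frame(participant_id = p$participant_id,
               household_id = p$household_id,
               hi_score = hi, vc_score = vc,
               hi_high = hi_split$high, vc_high = vc_split$high),
    flags)
  rownames(coded) <- NULL
  list(coded = coded, hi_median = hi_split$median,
       vc_median = vc_split$median,
       alpha_hi = cronbach_alpha(p[paste0("hi", 1:4)]),
       alpha_vc = cronbach_alpha(p[paste0("vc", 1:4)]))
}
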