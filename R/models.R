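#' @title Dyadic mixed models and diet models
#' @description The two model families of the analysis: cross-classified
#'   linear mixed models of directed health-importance ratings, and
#'   cluster-correlated logistic models of dichotomized diet outcomes on
#'   network-average characteristics.
#' @name models
NULL

#' Fit the cross-classified dyadic mixed model
#'
#' Linear mixed model of the 0--9 "importance of source in target's health"
#' rating on directed dyad records, with crossed random intercepts for
#' source node, target node and household (the cross-classified structure
#' that accommodates overlapping egocentric networks). Fixed effects per
#' specification:
#' \describe{
#'   \item{1}{interaction frequency, emotional closeness, relationship
#'     category (friend reference; intergenerational split by direction),
#'     and source/target age band, sex, health and effort.}
#'   \item{2}{specification 1 plus frequency of eating together.}
#'   \item{3}{specification 2 restricted to records whose source node is a
#'     surveyed participant, adding the above-median individualism and
#'     collectivism flags.}
#' }
#' Rows with any missing model variable are dropped listwise and the count
#' reported.
#'
#' @param records directed dyad records ([build_directed_records()] output,
#'   pooled over households); for specification 3 the records must carry
#'   \code{source_hi_high}/\code{source_vc_high} (see [attach_scale_flags()]).
#' @param model_spec 1, 2 or 3.
#' @param surveyed_only restrict to records where both endpoints are surveyed
#'   participants (sensitivity analysis).
#' @param node_effect_mode "crossed" (separate source and target intercepts,
#'   default) or "shared" (one intercept per node regardless of role,
#'   fitted via the modular lme4 interface by summing the two membership
#'   matrices).
#' @return a \code{dyad_fit}: list with \code{fit} (merMod), \code{tidy}
#'   (coefficient table with Wald 95% CIs), \code{n_used},
#'   \code{n_dropped}, \code{converged}.
#' @export
fit_dyad_mixed <- function(records, model_spec = 1, surveyed_only = FALSE,
                           node_effect_mode = c("crossed", "shared")) {
  node_effect_mode <- match.arg(node_effect_mode)
  stopifnot(model_spec %in% 1:3)
  d <- records
  if (surveyed_only)
    d <- d[d$source_surveyed & d$target_surveyed, , drop = FALSE]
  if (model_spec == 3) {
    if (!("source_hi_high" %in% names(d)))
      stop("specification 3 needs source_hi_high/source_vc_high columns; ",
           "run attach_scale_flags() first", call. = FALSE)
    d <- d[d$source_surveyed, , drop = FALSE]
  }
  d$category_dir <- ifelse(
    d$category == "intergenerational",
    paste0("intergenerational_", d$direction_subtype), d$category)
  d$category_dir <- stats::relevel(factor(d$category_dir), ref = "friend")
  d$source_band <- age_band(d$source_age)
  d$target_band <- age_band(d$target_age)
  fixed <- c("interact_freq", "closeness",
             if (model_spec >= 2) "eat_freq",
             "category_dir", "source_band", "source_sex", "source_health",
             "source_effort", "target_band", "target_sex", "target_health",
             "target_effort",
             if (model_spec == 3) c("source_hi_high", "source_vc_high"))
  vars <- c("outcome", "source_node", "target_node", "household_id", fixed)
  cc <- stats::complete.cases(d[, intersect(vars, names(d)), drop = FALSE])
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < 20)
    stop("sample-size error: only ", nrow(d), " complete records",
         call. = FALSE)
  # drop constant factors (e.g. single age band in a small simulation)
  fixed <- Filter(function(v) {
    x <- d[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, fixed)
  fml <- stats::as.formula(paste(
    "outcome ~", paste(fixed, collapse = " + "),
    "+ (1 | source_node) + (1 | target_node) + (1 | household_id)"))
  fit <- if (node_effect_mode == "crossed") {
    suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  } else {
    .lmer_shared_node(fml, d)
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  tidy <- data.frame(term = names(est), estimate = unname(est),
                     se = unname(se),
                     ci_low = unname(est - z * se),
                     ci_high = unname(est + z * se), row.names = NULL)
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(list(fit = fit, tidy = tidy, n_used = nrow(d),
                 n_dropped = n_dropped, model_spec = model_spec,
                 surveyed_only = surveyed_only, converged = conv),
            class = "dyad_fit")
}

# single random effect per node across source and target roles: build the
# crossed-model structure, then replace the two node membership matrices by
# their sum over a common level set before optimizing
.lmer_shared_node <- function(fml, d) {
  lev <- sort(unique(c(d$source_node, d$target_node)))
  d$source_node <- factor(d$source_node, levels = lev)
  d$target_node <- factor(d$target_node, levels = lev)
  lmod <- lme4::lFormula(fml, data = d, REML = TRUE,
                         control = lme4::lmerControl(
                           check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore"))
  flist <- lmod$reTrms$flist
  nms <- names(lmod$reTrms$cnms)
  i_src <- which(nms == "source_node")
  i_tgt <- which(nms == "target_node")
  n_lev <- length(lev)
  # rows of Zt are grouped by term in cnms order
  starts <- cumsum(c(1, vapply(seq_along(nms), function(i)
    length(lev_of <- levels(flist[[nms[i]]])) * length(lmod$reTrms$cnms[[i]]),
    numeric(1))))
  Zt <- lmod$reTrms$Zt
  rs <- function(i) seq(starts[i], starts[i + 1] - 1)
  Z_shared <- Zt[rs(i_src), , drop = FALSE] + Zt[rs(i_tgt), , drop = FALSE]
  keep_terms <- setdiff(seq_along(nms), i_tgt)
  blocks <- lapply(keep_terms, function(i)
    if (i == i_src) Z_shared else Zt[rs(i), , drop = FALSE])
  lmod$reTrms$Zt <- do.call(rbind, blocks)
  lmod$reTrms$cnms <- lmod$reTrms$cnms[keep_terms]
  lmod$reTrms$flist <- flist[names(flist)[keep_terms]]
  lmod$reTrms$theta <- rep(1, length(keep_terms))
  lmod$reTrms$lower <- rep(0, length(keep_terms))
  # Lambdat: diagonal, one theta per term block
  sizes <- vapply(blocks, nrow, numeric(1))
  ntot <- sum(sizes)
  lmod$reTrms$Lambdat <- Matrix::sparseMatrix(i = seq_len(ntot),
                                              j = seq_len(ntot),
                                              x = rep(1, ntot))
  lmod$reTrms$Lind <- rep(seq_along(sizes), times = sizes)
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devfun)
  lme4::mkMerMod(environment(devfun), opt, lmod$reTrms, fr = lmod$fr)
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat("dyadic mixed model (specification ", x$model_spec, "), n = ",
      x$n_used, " directed records (", x$n_dropped, " dropped)\n", sep = "")
  if (!x$converged) cat("WARNING: convergence not clean\n")
  print(x$tidy, digits = 3)
  invisible(x)
}

#' Attach scale flags to directed records
#'
#' Joins the above-median individualism/collectivism flags of the source
#' participant (where surveyed) onto directed dyad records, as needed for
#' model specification 3.
#'
#' @param records directed dyad records.
#' @param coded coded participant table from [code_participants()].
#' @return records with source_hi_high and source_vc_high columns.
#' @export
attach_scale_flags <- function(records, coded) {
  i <- match(records$source_participant, coded$participant_id)
  records$source_hi_high <- coded$hi_high[i]
  records$source_vc_high <- coded$vc_high[i]
  records
}

#' Per-participant network averages
#'
#' For one surveyed participant, the mean perceived health and effort of
#' network members (self-reports take precedence for surveyed members) and
#' the mean frequency of eating together over the participant's own ties,
#' computed over three scopes: the full network, family members excluding
#' the participant's spouse/partner, and friends only (the friend nodes the
#' participant themselves named, since friends are not shared household
#' members). A scope with zero members yields no row.
#'
#' @param network a \code{household_network}.
#' @param participant_id id of a surveyed participant in the network.
#' @return data frame with columns participant_id, scope, avg_health,
#'   avg_effort, avg_eat_freq, n_members.
#' @export
compute_network_averages <- function(network, participant_id) {
  reg <- network$registry
  self_idx <- match(participant_id, reg$participant_id)
  if (is.na(self_idx))
    stop("integrity error: participant ", participant_id,
         " not in network registry", call. = FALSE)
  self_id <- reg$node_id[self_idx]
  e <- network$edges
  couples <- attr(reg, "couples")
  spouse_of_self <- unique(c(
    unlist(Filter(function(cp) self_id %in% cp, couples)),
    e$a[e$category == "spouse_partner" & e$b == self_id],
    e$b[e$category == "spouse_partner" & e$a == self_id]))
  spouse_of_self <- setdiff(spouse_of_self, self_id)
  others <- reg[reg$node_id != self_id, , drop = FALSE]
  named <- unique(unname(attr(reg, "ref_map")[[participant_id]]))
  scopes <- list(
    full = others$node_id,
    family_excl_spouse = setdiff(
      others$node_id[kin_is_family(others$term)], spouse_of_self),
    friends = intersect(others$node_id[others$term == "friend"], named))
  rows <- list()
  for (sc in names(scopes)) {
    ids <- scopes[[sc]]
    if (!length(ids)) next
    m <- reg[match(ids, reg$node_id), , drop = FALSE]
    inc <- e[(e$a == self_id & e$b %in% ids) |
               (e$b == self_id & e$a %in% ids), , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = participant_id, scope = sc,
      avg_health = if (all(is.na(m$health))) NA_real_
                   else mean(m$health, na.rm = TRUE),
      avg_effort = if (all(is.na(m$effort))) NA_real_
                   else mean(m$effort, na.rm = TRUE),
      avg_eat_freq = if (!nrow(inc) || all(is.na(inc$eat_freq))) NA_real_
                     else mean(inc$eat_freq, na.rm = TRUE),
      n_members = length(ids))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Network averages for every surveyed participant
#'
#' @param networks list of \code{household_network} objects.
#' @return pooled data frame of [compute_network_averages()] rows.
#' @export
cohort_network_averages <- function(networks) {
  out <- do.call(rbind, lapply(networks, function(nw) {
    ids <- nw$registry$participant_id[nw$registry$surveyed]
    do.call(rbind, lapply(ids, function(pid)
      compute_network_averages(nw, pid)))
  }))
  rownames(out) <- NULL
  out
}

#' Logistic GEE of a diet outcome on network averages
#'
#' Models one dichotomized diet flag on the scope-specific network averages
#' (perceived health, effort, eating together; odds ratios per 1 rating
#' point), adjusted for participant age band, sex, race, income, BMI,
#' self-rated health and effort, with households as clusters, an
#' exchangeable working correlation and robust standard errors.
#'
#' @param participants pooled participants data frame.
#' @param coded coded table from [code_participants()].
#' @param averages pooled averages from [cohort_network_averages()].
#' @param outcome one of "veg_meets", "fruit_meets", "fastfood_none",
#'   "snacks_low".
#' @param scope one of "full", "family_excl_spouse", "friends".
#' @param corstr working correlation, default exchangeable.
#' @param adjusted include the covariate set (TRUE, the reported models) or
#'   fit network averages only.
#' @return a \code{gee_fit} with a \code{tidy} element (OR scale).
#' @export
fit_diet_gee <- function(participants, coded, averages, outcome,
                         scope = c("full", "family_excl_spouse", "friends"),
                         corstr = "exchangeable", adjusted = TRUE) {
  scope <- match.arg(scope)
  outcome <- match.arg(outcome, c("veg_meets", "fruit_meets",
                                  "fastfood_none", "snacks_low"))
  av <- averages[averages$scope == scope, , drop = FALSE]
  d <- merge(coded, av, by = "participant_id")
  d <- merge(d, participants[, c("participant_id", "age", "sex", "race",
                                 "income", "bmi", "self_health",
                                 "self_effort")], by = "participant_id")
  d$y <- as.numeric(d[[outcome]])
  d$band <- age_band(d$age)
  if (length(unique(stats::na.omit(d$y))) < 2)
    stop("sample error: outcome '", outcome, "' has a single level",
         call. = FALSE)
  covars <- if (adjusted) {
    keep <- Filter(function(v) length(unique(stats::na.omit(d[[v]]))) > 1,
                   c("band", "sex", "race", "income", "bmi", "self_health",
                     "self_effort"))
    paste(c("avg_health", "avg_effort", "avg_eat_freq", keep), collapse = " + ")
  } else "avg_health + avg_effort + avg_eat_freq"
  fml <- stats::as.formula(paste("y ~", covars))
  fit <- gee_logit(fml, d, id = "household_id", corstr = corstr)
  fit$tidy <- tidy_gee(fit)
  fit$outcome <- outcome
  fit$scope <- scope
  fit
}
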