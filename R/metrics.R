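#' @title Network descriptives and assortativity
#' @description Per-network and pooled descriptives (size, category-wise
#'   rating means) and attribute assortativity weighted by tie strength
#'   (eating together or mutual health importance).
#' @name network_metrics
NULL

.edge_categories <- c("intergenerational", "intragenerational",
                      "spouse_partner", "friend", "other")

#' Cohort network-size summary
#'
#' Per-network node/edge counts and per-category edge counts, plus cohort
#' mean and sd (n-1 denominator; sd is NA for a single network).
#'
#' @param networks list of \code{household_network} objects.
#' @return list with \code{per_network} (data frame) and \code{cohort}
#'   (data frame of mean/sd of node and edge counts).
#' @export
summarize_networks <- function(networks) {
  stopifnot(length(networks) >= 1)
  per <- do.call(rbind, lapply(networks, function(nw) {
    counts <- table(factor(nw$edges$category, levels = .edge_categories))
    cbind(data.frame(household_id = nw$household_id,
                     n_nodes = nrow(nw$registry), n_edges = nrow(nw$edges)),
          as.data.frame.matrix(t(as.matrix(counts))))
  }))
  rownames(per) <- NULL
  sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  cohort <- data.frame(
    measure = c("n_nodes", "n_edges"),
    mean = c(mean(per$n_nodes), mean(per$n_edges)),
    sd = c(sd_or_na(per$n_nodes), sd_or_na(per$n_edges)))
  list(per_network = per, cohort = cohort)
}

#' Category-wise means of directed tie ratings
#'
#' Means of interaction frequency, emotional closeness, eating together and
#' health importance over directed records pooled across households, by
#' relationship category; the importance mean for intergenerational ties is
#' additionally split by whether the target node sits in an older or younger
#' generation than the source. Categories absent from every network yield no
#' row (missing cell, not zero).
#'
#' @param networks list of \code{household_network} objects.
#' @return data frame with columns category, direction, n_records and the
#'   four means.
#' @export
category_means <- function(networks) {
  rec <- do.call(rbind, lapply(networks, build_directed_records))
  if (is.null(rec) || !nrow(rec)) return(data.frame())
  grp <- ifelse(rec$category == "intergenerational",
                paste(rec$category, rec$direction_subtype, sep = "|"),
                paste(rec$category, "same", sep = "|"))
  m <- function(x) tapply(x, grp, function(v) mean(v, na.rm = TRUE))
  ks <- sort(unique(grp))
  out <- data.frame(
    category = sub("\\|.*", "", ks),
    direction = sub(".*\\|", "", ks),
    n_records = as.integer(table(grp)[ks]),
    interact_freq = as.numeric(m(rec$interact_freq)[ks]),
    closeness = as.numeric(m(rec$closeness)[ks]),
    eat_freq = as.numeric(m(rec$eat_freq)[ks]),
    importance = as.numeric(m(rec$outcome)[ks]))
  rownames(out) <- NULL
  out
}

.edge_weights <- function(network, weight) {
  e <- network$edges
  switch(weight,
         eat_freq = e$eat_freq,
         importance = rowMeans(cbind(e$importance_ab, e$importance_ba),
                               na.rm = TRUE),
         stop("unknown weight '", weight, "'", call. = FALSE))
}

.node_attr <- function(network, attribute) {
  reg <- network$registry
  switch(attribute,
         age = reg$age,
         sex = reg$sex,
         self_health = reg$health,
         self_effort = reg$effort,
         stop("unknown attribute '", attribute, "'", call. = FALSE))
}

#' Weighted numeric assortativity
#'
#' Weighted Pearson correlation of endpoint attribute values over the
#' symmetrized edge list (each undirected edge contributes both orderings),
#' with each ordered pair weighted by the chosen tie rating. With equal
#' weights this reduces to the classical (Newman) numeric assortativity
#' coefficient. Edges with zero weight or a missing endpoint attribute
#' contribute nothing.
#'
#' @param network a \code{household_network}.
#' @param attribute one of "age", "self_health", "self_effort".
#' @param weight one of "eat_freq" (frequency of eating together) or
#'   "importance" (mean of the two directed health-importance ratings).
#' @return coefficient in [-1, 1], or NA when undefined (zero total weight
#'   or zero attribute variance among weighted endpoints).
#' @export
assortativity_numeric <- function(network, attribute,
                                  weight = c("eat_freq", "importance")) {
  weight <- match.arg(weight)
  x_all <- .node_attr(network, attribute)
  if (!is.numeric(x_all)) stop("attribute must be numeric", call. = FALSE)
  e <- network$edges
  w <- .edge_weights(network, weight)
  ai <- match(e$a, network$registry$node_id)
  bi <- match(e$b, network$registry$node_id)
  keep <- !is.na(w) & w > 0 & !is.na(x_all[ai]) & !is.na(x_all[bi])
  if (!any(keep)) return(NA_real_)
  xs <- c(x_all[ai[keep]], x_all[bi[keep]])
  ys <- c(x_all[bi[keep]], x_all[ai[keep]])
  ws <- c(w[keep], w[keep])
  W <- sum(ws)
  mx <- sum(ws * xs) / W
  vx <- sum(ws * (xs - mx)^2) / W
  if (vx <= .Machine$double.eps) return(NA_real_)
  # symmetrization makes the two marginals identical
  sum(ws * (xs - mx) * (ys - mx)) / W / vx
}

#' Weighted categorical assortativity
#'
#' Newman mixing-matrix assortativity \eqn{r = (\sum_i e_{ii} - \sum_i a_i
#' b_i) / (1 - \sum_i a_i b_i)} on the weight-normalized symmetric mixing
#' matrix. A perfectly within-category network gives +1; a complete
#' bipartite cross-category network gives -1.
#'
#' @param network a \code{household_network}.
#' @param attribute categorical node attribute ("sex").
#' @param weight as in [assortativity_numeric()].
#' @return coefficient in [-1, 1], or NA when undefined (zero weight or a
#'   single category present).
#' @export
assortativity_categorical <- function(network, attribute = "sex",
                                      weight = c("eat_freq", "importance")) {
  weight <- match.arg(weight)
  x_all <- as.character(.node_attr(network, attribute))
  e <- network$edges
  w <- .edge_weights(network, weight)
  ai <- match(e$a, network$registry$node_id)
  bi <- match(e$b, network$registry$node_id)
  keep <- !is.na(w) & w > 0 & !is.na(x_all[ai]) & !is.na(x_all[bi])
  if (!any(keep)) return(NA_real_)
  ca <- x_all[ai[keep]]; cb <- x_all[bi[keep]]; ws <- w[keep]
  lev <- sort(unique(c(ca, cb)))
  if (length(lev) < 2) return(NA_real_)
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(ws)) {
    m[ca[i], cb[i]] <- m[ca[i], cb[i]] + ws[i]
    m[cb[i], ca[i]] <- m[cb[i], ca[i]] + ws[i]
  }
  m <- m / sum(m)
  ab <- sum(rowSums(m) * colSums(m))
  if (abs(1 - ab) <= .Machine$double.eps) return(NA_real_)
  (sum(diag(m)) - ab) / (1 - ab)
}

#' Cohort assortativity table
#'
#' Runs both assortativity estimators over every network for the study's
#' attribute/weight grid (age, sex, self-rated health, effort, each weighted
#' by eating together and by mutual health importance) and summarises the
#' defined coefficients (mean, sd, number of networks where the coefficient
#' was undefined and hence dropped).
#'
#' @param networks list of \code{household_network} objects.
#' @param attributes character vector of attributes; "sex" uses the
#'   categorical estimator, others the numeric one.
#' @param weights character vector of weights.
#' @return data frame with one row per attribute x weight.
#' @export
assortativity_cohort <- function(networks,
                                 attributes = c("age", "sex", "self_health",
                                                "self_effort"),
                                 weights = c("eat_freq", "importance")) {
  rows <- list()
  for (at in attributes) {
    for (w in weights) {
      coefs <- vapply(networks, function(nw) {
        if (at == "sex") assortativity_categorical(nw, at, w)
        else assortativity_numeric(nw, at, w)
      }, numeric(1))
      ok <- coefs[!is.na(coefs)]
      rows[[length(rows) + 1]] <- data.frame(
        attribute = at, weight = w, n_networks = length(ok),
        n_undefined = sum(is.na(coefs)),
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1) stats::sd(ok) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
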