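#' @title GEE logistic regression
#' @description Generalized estimating equations for clustered binary
#'   outcomes with an exchangeable (or independence) working correlation and
#'   cluster-robust (sandwich) standard errors. Population-average logistic
#'   coefficients; with singleton clusters or an independence working
#'   correlation the point estimates coincide with ordinary logistic
#'   regression.
#' @name gee
NULL

#' Fit a logistic GEE
#'
#' Fisher-scoring solution of the estimating equations
#' \eqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0} with logit link,
#' \eqn{V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}}; the exchangeable
#' correlation \eqn{\alpha} and scale \eqn{\phi} are moment-estimated from
#' Pearson residuals each iteration. Variances are the robust sandwich
#' estimator, so inference is valid even when the working correlation is
#' wrong.
#'
#' @param formula model formula for the binary outcome.
#' @param data data frame; rows with missing model variables are dropped
#'   listwise (the fit records how many).
#' @param id cluster identifier (bare column name as string).
#' @param corstr "exchangeable" or "independence".
#' @param maxit,tol iteration control.
#' @return object of class \code{gee_fit}: coefficients, robust vcov, alpha,
#'   phi, n_obs, n_clusters, n_dropped, converged.
#' @export
gee_logit <- function(formula, data, id, corstr = c("exchangeable",
                                                    "independence"),
                      maxit = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  mf_all <- stats::model.frame(formula, data, na.action = stats::na.pass)
  cluster_all <- data[[id]]
  keep <- stats::complete.cases(mf_all) & !is.na(cluster_all)
  n_dropped <- sum(!keep)
  mf <- mf_all[keep, , drop = FALSE]
  cluster <- as.character(cluster_all[keep])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  if (all(y == y[1]))
    stop("sample error: outcome is constant; cannot fit", call. = FALSE)
  p <- ncol(X)
  # initialize at the ordinary logistic solution
  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit0$coefficients
  if (anyNA(beta))
    stop("sample error: design matrix is rank-deficient", call. = FALSE)
  idx <- split(seq_along(y), cluster)
  alpha <- 0
  phi <- 1
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-10)) separated <- TRUE
    v <- pmax(v, 1e-10)
    pr <- (y - mu) / sqrt(v)
    # moment estimates of scale and exchangeable correlation
    phi <- sum(pr^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni > 1) {
          s <- sum(pr[ix])
          num <- num + (s^2 - sum(pr[ix]^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha <- if (den > p) num / ((den - p) * phi) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    U <- numeric(p)
    H <- matrix(0, p, p)
    for (ix in idx) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      Ai <- v[ix]
      Di <- Xi * Ai                       # d mu / d beta
      Ri <- if (corstr == "exchangeable" && ni > 1)
        matrix(alpha, ni, ni) + diag(1 - alpha, ni) else diag(1, ni)
      Vi <- phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri
      Vinv <- solve(Vi)
      U <- U + drop(crossprod(Di, Vinv %*% (y[ix] - mu[ix])))
      H <- H + crossprod(Di, Vinv %*% Di)
    }
    step <- solve(H, U)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  # robust sandwich variance at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- pmax(mu * (1 - mu), 1e-10)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in idx) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    Ai <- v[ix]
    Di <- Xi * Ai
    Ri <- if (corstr == "exchangeable" && ni > 1)
      matrix(alpha, ni, ni) + diag(1 - alpha, ni) else diag(1, ni)
    Vinv <- solve(phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri)
    ei <- y[ix] - mu[ix]
    gi <- crossprod(Di, Vinv %*% ei)
    B <- B + crossprod(Di, Vinv %*% Di)
    M <- M + gi %*% t(gi)
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = vcov_robust, alpha = alpha, phi = phi,
                 corstr = corstr, n_obs = length(y),
                 n_clusters = length(idx), n_dropped = n_dropped,
                 converged = converged, separated = separated,
                 formula = formula),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE logistic fit (", x$corstr, " working correlation)\n", sep = "")
  cat("clusters:", x$n_clusters, " obs:", x$n_obs,
      " dropped:", x$n_dropped, "\n")
  if (!x$converged) cat("WARNING: did not converge\n")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, robust_se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Tidy a GEE fit on the odds-ratio scale
#'
#' @param fit a \code{gee_fit}.
#' @param conf_level confidence level for Wald intervals.
#' @return data frame: term, estimate (log-odds), se, or, ci_low, ci_high
#'   (OR scale), n, converged.
#' @export
tidy_gee <- function(fit, conf_level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(se),
             or = exp(unname(fit$coefficients)),
             ci_low = exp(unname(fit$coefficients - z * se)),
             ci_high = exp(unname(fit$coefficients + z * se)),
             n = fit$n_obs, converged = fit$converged & !fit$separated,
             row.names = NULL)
}
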