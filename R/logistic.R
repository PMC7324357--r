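#' Binary logistic regression with Wald intervals
#'
#' Maximum-likelihood fit by Newton-Raphson / iteratively reweighted least
#' squares: starting from zero coefficients, iterate until the score
#' (gradient) norm falls below `tol` or `max_iter` is reached. Odds ratios
#' are `exp(coef)` with Wald 95\% confidence limits (LCL, UCL), matching the
#' presentation of clinical multivariable tables.
#'
#' Degenerate designs are reported, not silently fitted: covariates constant
#' across patients raise an error naming them, and complete or
#' quasi-separation (coefficients diverging, standard errors exploding) raises
#' a structured error naming the offending covariate.
#'
#' @param x numeric matrix of covariates (no intercept column; one is added).
#' @param y binary outcome vector (0/1 or logical), e.g. the SCLC indicator.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `logistic_fit`: coefficients, `se`, `odds_ratio`,
#'   `lcl`, `ucl`, `p_value` (Wald), `converged`, `n_iter`, `n_events`
#'   (count of covariate = 1 for binary covariates, `NA` otherwise),
#'   `loglik`, `fitted`.
#' @export
logistic_fit <- function(x, y, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (anyNA(x) || anyNA(y)) stop("missing covariates/outcomes; exclude listwise first")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event")
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))

  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("degenerate covariate (constant across patients): ",
         paste(colnames(x)[const], collapse = ", "))

  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  beta <- stats::setNames(rep(0, p), colnames(xd))
  converged <- FALSE
  iter_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(xd, y - mu))
    iter_trace[it] <- sqrt(sum(score^2))
    if (iter_trace[it] < tol) { converged <- TRUE; break }
    info <- crossprod(xd, xd * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix (collinear covariates)")
    # dampen huge steps so near-separated fits diverge gracefully
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
  }

  eta <- drop(xd %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(xd, xd * (mu * (1 - mu)))
  cov_beta <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov_beta)) rep(Inf, p) else sqrt(diag(cov_beta))

  # separation: diverging coefficients / exploding SEs on a covariate
  suspect <- (abs(beta) > 15 | se > 100) & names(beta) != "(Intercept)"
  if (!converged || any(suspect)) {
    if (any(suspect))
      stop(sprintf("separation detected: covariate(s) %s perfectly (or quasi-) separate the outcome",
                   paste(names(beta)[suspect], collapse = ", ")))
    stop("logistic fit did not converge in ", max_iter,
         " iterations; score-norm trace: ",
         paste(signif(utils::tail(iter_trace, 5), 3), collapse = " -> "))
  }

  z <- stats::qnorm(0.975)
  n_events <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (all(v %in% c(0, 1))) sum(v == 1) else NA_integer_
  }, 1L)
  names(n_events) <- colnames(x)

  structure(list(
    coefficients = beta, se = se,
    odds_ratio = exp(beta), lcl = exp(beta - z * se), ucl = exp(beta + z * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged, n_iter = it, n_events = n_events,
    loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)),
    fitted = mu
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (Newton/IRLS), converged in", x$n_iter, "iterations\n")
  tab <- data.frame(OR = x$odds_ratio, LCL = x$lcl, UCL = x$ucl,
                    p = signif(x$p_value, 3))
  print(round(tab, 3))
  invisible(x)
}
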