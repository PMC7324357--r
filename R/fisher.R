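#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by probability-mass summation: conditioning on the
#' margins, the p-value is the sum of hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (with
#' a relative slack of 1e-7 to absorb floating-point ties) — the convention
#' used by mainstream clinical statistics software.
#'
#' The odds ratio is the sample cross-product ratio `(a*d)/(b*c)` with a
#' Woolf (log-normal) 95\% confidence interval; when any cell is zero the
#' Haldane-Anscombe correction (adding 0.5 to every cell) is applied to both
#' the estimate and the interval and flagged in the result.
#'
#' @param table 2x2 numeric matrix of counts, rows = outcome groups
#'   (conventionally row 1 = SCLC, row 2 = NT), columns = exposed/unexposed.
#'   Alternatively pass the four counts `a, b, c, d` (row-wise).
#' @param a,b,c,d individual cell counts, used when `table` is missing.
#' @param conf confidence level for the odds-ratio interval.
#' @return object of class `fisher_result`: list with `p_two_sided`,
#'   `odds_ratio`, `or_ci_95`, `haldane`, `table`.
#' @examples
#' fisher_exact(matrix(c(29, 15, 7, 36), 2, byrow = TRUE))  # smoking, SCLC vs NT
#' @export
fisher_exact <- function(table, a, b, c, d, conf = 0.95) {
  if (missing(table)) {
    table <- matrix(base::c(a, b, c, d), 2, byrow = TRUE)
  }
  fisher_exact_impl(as.matrix(table), conf)
}

fisher_exact_impl <- function(table, conf) {
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: an empty margin leaves nothing to test")

  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row-1 total
  n <- c_ + d         # row-2 total
  k <- a + c_         # column-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  haldane <- any(table == 0)
  tt <- if (haldane) table + 0.5 else table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se_log <- sqrt(sum(1 / tt))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se_log)

  structure(list(p_two_sided = p, odds_ratio = or,
                 or_ci_95 = c(lower = ci[1], upper = ci[2]),
                 haldane = haldane, table = table),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided)\n")
  cat(sprintf("  p = %.4g; OR = %.3f (95%% CI %.3f to %.3f)%s\n",
              x$p_two_sided, x$odds_ratio, x$or_ci_95[1], x$or_ci_95[2],
              if (x$haldane) " [Haldane-Anscombe 0.5 correction]" else ""))
  invisible(x)
}
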