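#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @details The Wilson interval keeps sensible coverage in the small strata
#'   (n of 1-20 per score) that arise in per-score risk tables, unlike the
#'   Wald interval which collapses at 0 and 1.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# round a proportion to a whole percentage the way the clinical tables print
# it: half-up to one decimal, then half-up to an integer (so 20.45% -> 20.5%
# -> 21%, 95.45% -> 96%), never banker's rounding
pct <- function(x, n) {
  p <- 100 * x / n
  one_dp <- floor(p * 10 + 0.5) / 10
  ifelse(n > 0, floor(one_dp + 0.5), NA_real_)
}

# stable non-cryptographic hash (FNV-1a, 32-bit) of a character scalar;
# used for run manifests so reruns on identical input are byte-identical
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double to stay 32-bit safe
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, in double arithmetic:
    # split h to keep intermediate products inside 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
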