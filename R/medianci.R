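#' Sample median with an exact order-statistic confidence interval
#'
#' The 95\% interval is the pair of symmetric order statistics
#' (x_(k), x_(n+1-k)) with the largest k whose exact binomial coverage
#' 1 - 2 P(Binom(n, 1/2) < k) is at least the requested level — the
#' distribution-free interval appropriate for the small skewed samples
#' (scores, titres, survival months) summarised by medians in clinical
#' tables. For n below 6 no such interval reaches 95\%; the whole sample
#' range is returned with a warning.
#'
#' @param values numeric sample, n >= 1.
#' @param conf confidence level.
#' @return list with `median`, `ci_95` (`c(lower, upper)`), `coverage`
#'   (achieved exact coverage), `n`.
#' @export
median_with_ci <- function(values, conf = 0.95) {
  values <- sort(as.numeric(values))
  n <- length(values)
  stopifnot(n >= 1)
  med <- stats::median(values)
  if (n < 6) {
    warning("n < 6: no order-statistic interval reaches ", conf,
            " coverage; returning the sample range", call. = FALSE)
    return(list(median = med, ci_95 = c(lower = values[1], upper = values[n]),
                coverage = 1 - 2 * stats::pbinom(0, n, 0.5), n = n))
  }
  ks <- seq_len(floor(n / 2))
  coverage <- 1 - 2 * stats::pbinom(ks - 1, n, 0.5)
  k <- max(ks[coverage >= conf])
  list(median = med,
       ci_95 = c(lower = values[k], upper = values[n + 1 - k]),
       coverage = coverage[ks == k], n = n)
}
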