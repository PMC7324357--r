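#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator. With no censoring it coincides with the empirical
#' survival function.
#'
#' @param time non-negative event/censoring times.
#' @param event 1 = event (death), 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (one row per distinct event or censoring time, in increasing order).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0), all(event %in% c(0, 1)))
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

# median survival: first time the KM curve drops to 0.5 or below;
# NA when the curve never crosses 0.5
km_median <- function(curve) {
  idx <- which(curve$surv <= 0.5 + 1e-12)
  if (length(idx) == 0) return(NA_real_)
  curve$time[idx[1]]
}

#' Two-group survival comparison: Kaplan-Meier medians and log-rank test
#'
#' Unstratified two-group log-rank: at each distinct event time the observed
#' deaths in group 1 are compared with their hypergeometric expectation given
#' the risk sets, and the chi-square statistic (1 df) is
#' `(O - E)^2 / Var`.
#'
#' @param time non-negative times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level grouping vector (e.g. `"SCLC"` / `"NT"`).
#' @return object of class `survival_summary`: per-group `curves` (list of
#'   [km_curve()] frames), `medians`, `chisq`, `df`, `p_value`, `n`, `n_events`.
#' @export
survival_compare <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- as.character(group[keep])
  levels <- sort(unique(group))
  if (length(levels) != 2) stop("survival_compare needs exactly two groups")
  if (sum(event) == 0) stop("log-rank undefined: no events in either group")

  g1 <- group == levels[1]
  curves <- lapply(levels, function(l) km_curve(time[group == l], event[group == l]))
  names(curves) <- levels
  medians <- vapply(curves, km_median, 0)

  dtimes <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in dtimes) {
    n1 <- sum(g1 & time >= t); n2 <- sum(!g1 & time >= t)
    d1 <- sum(g1 & time == t & event == 1)
    d2 <- sum(!g1 & time == t & event == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  structure(list(curves = curves, medians = medians, chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 n = as.vector(table(factor(group, levels))),
                 n_events = vapply(levels, function(l) sum(event[group == l]), 0)),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat("Kaplan-Meier comparison\n")
  for (l in names(x$curves))
    cat(sprintf("  %s: median %.3g months\n", l, x$medians[l]))
  cat(sprintf("  log-rank chi-square = %.3f (1 df), p = %.4g\n", x$chisq, x$p_value))
  invisible(x)
}
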