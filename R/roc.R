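#' Empirical ROC operating points for an ordinal score
#'
#' One operating point per distinct threshold s under the rule "score >= s is
#' called positive", plus the trivial (0,0) and (1,1) corners. Sensitivity
#' and specificity are exact fractions of the case/control counts.
#'
#' @param scores numeric/ordinal score per patient.
#' @param labels case/control indicator: logical, 0/1, or a two-level factor
#'   where the higher level (or `TRUE`/1/"SCLC") marks cases.
#' @return data.frame with `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, ordered from the all-negative corner to
#'   the all-positive corner.
#' @export
roc_points <- function(scores, labels) {
  lab <- as_case_indicator(labels)
  stopifnot(length(scores) == length(lab), !anyNA(scores))
  if (all(lab) || !any(lab)) stop("need both cases and controls to draw a ROC curve")
  cases <- scores[lab]; controls <- scores[!lab]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(s) sum(cases >= s), 0)
  fp <- vapply(thr, function(s) sum(controls >= s), 0)
  data.frame(threshold = thr, tp = tp, fp = fp,
             tn = length(controls) - fp, fn = length(cases) - tp,
             sensitivity = tp / length(cases),
             specificity = (length(controls) - fp) / length(controls))
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  labels <- as.character(labels)
  if ("SCLC" %in% labels) return(labels == "SCLC")
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must have exactly two levels")
  labels == lv[2]
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties half-credited), and symmetrically for controls
placements <- function(cases, controls) {
  v10 <- vapply(cases, function(s)
    (sum(s > controls) + 0.5 * sum(s == controls)) / length(controls), 0)
  v01 <- vapply(controls, function(s)
    (sum(cases < s) + 0.5 * sum(cases == s)) / length(cases), 0)
  list(v10 = v10, v01 = v01)
}

#' Empirical AUC with DeLong variance and confidence interval
#'
#' AUC is the pairwise (Mann-Whitney) estimator: the probability that a
#' random case outscores a random control, ties credited one half. Its
#' standard error comes from the DeLong placement-value decomposition
#' `var = var(V10)/m + var(V01)/n`; the normal 95\% interval is clipped
#' to \[0, 1\].
#'
#' @inheritParams roc_points
#' @param conf confidence level.
#' @return object of class `auc_result`: `auc`, `se`, `ci_95`, `n_cases`,
#'   `n_controls`, `method = "empirical"`, and the placement values (used by
#'   [compare_auc_paired()]).
#' @export
auc_with_ci <- function(scores, labels, conf = 0.95) {
  lab <- as_case_indicator(labels)
  stopifnot(length(scores) == length(lab), !anyNA(scores))
  if (all(lab) || !any(lab)) stop("need both cases and controls")
  cases <- scores[lab]; controls <- scores[!lab]
  pl <- placements(cases, controls)
  auc <- mean(pl$v10)
  m <- length(cases); n <- length(controls)
  var_auc <- (if (m > 1) stats::var(pl$v10) / m else 0) +
             (if (n > 1) stats::var(pl$v01) / n else 0)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
  structure(list(auc = auc, se = se, ci_95 = ci, n_cases = m, n_controls = n,
                 method = "empirical", placements = pl),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.1f%% (95%% CI %.1f%% to %.1f%%); %d cases, %d controls\n",
              100 * x$auc, 100 * x$ci_95[1], 100 * x$ci_95[2],
              x$n_cases, x$n_controls))
  invisible(x)
}

#' Compare two AUCs measured on the same patients (paired, DeLong)
#'
#' For two scores of the same cohort the empirical AUCs are correlated; the
#' DeLong covariance `cov(V10a, V10b)/m + cov(V01a, V01b)/n` enters the
#' contrast `z = (AUCa - AUCb) / sqrt(var_a + var_b - 2 cov)` with a
#' two-sided normal p-value.
#'
#' @param scores_a,scores_b the two scores, same patients, same order.
#' @param labels case/control labels.
#' @return object of class `auc_comparison` with `delta_auc`, `z`,
#'   `p_two_sided`, `mode = "paired"`, `correlation_estimate`, and both
#'   `auc_result`s.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("paired comparison needs the two scores on the same patients")
  ra <- auc_with_ci(scores_a, labels)
  rb <- auc_with_ci(scores_b, labels)
  m <- ra$n_cases; n <- ra$n_controls
  cov_ab <- (if (m > 1) stats::cov(ra$placements$v10, rb$placements$v10) / m else 0) +
            (if (n > 1) stats::cov(ra$placements$v01, rb$placements$v01) / n else 0)
  var_d <- ra$se^2 + rb$se^2 - 2 * cov_ab
  delta <- ra$auc - rb$auc
  z <- if (var_d <= 1e-16) { if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
       } else delta / sqrt(var_d)
  corr <- if (ra$se > 0 && rb$se > 0) cov_ab / (ra$se * rb$se) else NA_real_
  structure(list(delta_auc = delta, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 mode = "paired", correlation_estimate = corr,
                 auc_a = ra, auc_b = rb),
            class = "auc_comparison")
}

#' Compare two AUCs from disjoint samples (independent)
#'
#' `z = (AUCa - AUCb) / sqrt(se_a^2 + se_b^2)`, two-sided normal p — the
#' contrast for subgroup AUCs (e.g. males vs females) estimated on
#' non-overlapping patients.
#'
#' @param result_a,result_b `auc_result` objects from disjoint samples, or
#'   bare lists with `auc` and `se`.
#' @return object of class `auc_comparison` with `mode = "independent"`.
#' @export
compare_auc_independent <- function(result_a, result_b) {
  stopifnot(!is.null(result_a$auc), !is.null(result_a$se),
            !is.null(result_b$auc), !is.null(result_b$se))
  delta <- result_a$auc - result_b$auc
  var_d <- result_a$se^2 + result_b$se^2
  z <- if (var_d <= 1e-16) { if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
       } else delta / sqrt(var_d)
  structure(list(delta_auc = delta, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 mode = "independent", correlation_estimate = NA_real_,
                 auc_a = result_a, auc_b = result_b),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("%s AUC comparison: delta = %.4f, z = %.3f, p = %.4g\n",
              x$mode, x$delta_auc, x$z, x$p_two_sided))
  invisible(x)
}

#' Exact score-level AUC implied by per-item probabilities
#'
#' Under item independence within each group, the score of a patient is a sum
#' of six Bernoulli items; convolving them gives the exact score distribution
#' on 0..6 per group, and the AUC is `P(S_case > S_control) + 0.5 P(equal)`.
#' Serves as the analytic oracle for the empirical estimator on simulated
#' cohorts.
#'
#' @param p_case,p_control vectors of item probabilities in \[0, 1\]
#'   (typically six, one per DELTA-P item).
#' @return list with `auc`, `dist_case`, `dist_control` (probability vectors
#'   over scores `0..k`).
#' @export
analytic_auc_from_item_probs <- function(p_case, p_control) {
  stopifnot(length(p_case) == length(p_control),
            all(p_case >= 0 & p_case <= 1), all(p_control >= 0 & p_control <= 1))
  convolve_bernoulli <- function(p) {
    d <- 1
    for (q in p) d <- c(d * (1 - q), 0) + c(0, d * q)
    d
  }
  dc <- convolve_bernoulli(p_case)
  dn <- convolve_bernoulli(p_control)
  k <- length(dc)
  cum_dn <- c(0, cumsum(dn))  # cum_dn[s+1] = P(control < s)
  auc <- sum(dc * (cum_dn[seq_len(k)] + 0.5 * dn))
  list(auc = auc, dist_case = dc, dist_control = dn)
}
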