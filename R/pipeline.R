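#' Univariable group comparison (Table-1 style)
#'
#' For each clinical variable: per-group counts and whole percentages for
#' binary variables with Fisher's exact p, medians with Mann-Whitney p for
#' numeric variables (age, VGCC titre), and Kaplan-Meier medians with the
#' log-rank p for survival. The erectile-dysfunction item is reported twice,
#' over all patients (females counted unaffected) and over males only.
#' Variables absent in every patient are marked unavailable rather than
#' dropped silently.
#'
#' @param cohort validated cohort data.frame with SCLC and NT groups.
#' @return data.frame of class `univariable_summary`: one row per variable
#'   with `variable`, `type`, per-group summaries, `p_value`, `test`.
#' @export
univariable_summary <- function(cohort) {
  cohort <- cohort[cohort$group %in% c("SCLC", "NT"), ]
  if (sum(cohort$group == "SCLC") < 1 || sum(cohort$group == "NT") < 1)
    stop("need at least one patient in each of the SCLC and NT groups")
  items <- derive_items(cohort)
  sclc <- cohort$group == "SCLC"

  rows <- list()
  add <- function(variable, type, s1, s2, p, test) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, type = type, sclc = s1, nt = s2,
      p_value = p, test = test, stringsAsFactors = FALSE)
  }

  binary_row <- function(name, flag) {
    ok <- !is.na(flag)
    if (!any(ok)) { add(name, "binary", "unavailable", "unavailable", NA, "none"); return() }
    a <- sum(flag[sclc & ok] == 1); na_ <- sum(sclc & ok)
    c_ <- sum(flag[!sclc & ok] == 1); nb <- sum(!sclc & ok)
    p <- tryCatch(fisher_exact(matrix(c(a, na_ - a, c_, nb - c_), 2, byrow = TRUE))$p_two_sided,
                  error = function(e) NA_real_)
    add(name, "binary",
        sprintf("%d/%d (%d%%)", a, na_, pct(a, na_)),
        sprintf("%d/%d (%d%%)", c_, nb, pct(c_, nb)),
        p, "fisher_exact")
  }
  numeric_row <- function(name, values) {
    ok <- !is.na(values)
    if (!any(ok & sclc) || !any(ok & !sclc)) {
      add(name, "numeric", "unavailable", "unavailable", NA, "none"); return() }
    xs <- values[sclc & ok]; ys <- values[!sclc & ok]
    p <- tryCatch(mann_whitney(xs, ys)$p_two_sided, error = function(e) NA_real_)
    add(name, "numeric",
        sprintf("%g (%g-%g)", stats::median(xs), min(xs), max(xs)),
        sprintf("%g (%g-%g)", stats::median(ys), min(ys), max(ys)),
        p, "mann_whitney")
  }

  numeric_row("age_years", cohort$age_years)
  binary_row("age_ge50", items$A)
  binary_row("female", as.integer(cohort$sex == "F"))
  binary_row("bulbar_weakness", items$D)
  binary_row("erectile_dysfunction_all", items$E)
  male <- cohort$sex == "M"
  if (any(male & sclc) && any(male & !sclc)) {
    em <- items$E[male]; sm <- sclc[male]; ok <- !is.na(em)
    a <- sum(em[sm & ok] == 1); na_ <- sum(sm & ok)
    c_ <- sum(em[!sm & ok] == 1); nb <- sum(!sm & ok)
    p <- tryCatch(fisher_exact(matrix(c(a, na_ - a, c_, nb - c_), 2, byrow = TRUE))$p_two_sided,
                  error = function(e) NA_real_)
    add("erectile_dysfunction_males", "binary",
        sprintf("%d/%d (%d%%)", a, na_, pct(a, na_)),
        sprintf("%d/%d (%d%%)", c_, nb, pct(c_, nb)), p, "fisher_exact")
  } else {
    add("erectile_dysfunction_males", "binary", "unavailable", "unavailable", NA, "none")
  }
  binary_row("weight_loss_ge5pct", items$L)
  binary_row("smoking_at_onset", items$T)
  binary_row("karnofsky_lt70", items$P)
  binary_row("vgcc_positive", as.integer(!is.na(cohort$vgcc_titre_pM)))
  numeric_row("vgcc_titre_pM", cohort$vgcc_titre_pM)

  if (any(!is.na(cohort$survival_months) & !is.na(cohort$death_event))) {
    sv <- tryCatch(
      survival_compare(cohort$survival_months, cohort$death_event, cohort$group),
      error = function(e) NULL)
    if (!is.null(sv)) {
      add("survival_months", "survival",
          sprintf("median %g", sv$medians["SCLC"]),
          sprintf("median %g", sv$medians["NT"]),
          sv$p_value, "log_rank")
    } else add("survival_months", "survival", "unavailable", "unavailable", NA, "none")
  } else add("survival_months", "survival", "unavailable", "unavailable", NA, "none")

  out <- do.call(rbind, rows)
  class(out) <- c("univariable_summary", "data.frame")
  out
}

#' Multivariable logistic model on the six DELTA-P items (Table-2 style)
#'
#' Fits SCLC ~ D + E + L + T + A + P by [logistic_fit()] on patients with all
#' six items non-missing (listwise exclusion, count reported). Per covariate:
#' number of events (patients with the item present), odds ratio, Wald 95\%
#' confidence limits and p-value.
#'
#' @param cohort validated cohort data.frame.
#' @return list of class `multivariable_summary`: `table` (one row per item),
#'   `n_included`, `n_excluded`, `fit` (the underlying `logistic_fit`).
#' @export
multivariable_summary <- function(cohort) {
  cohort <- cohort[cohort$group %in% c("SCLC", "NT"), ]
  items <- derive_items(cohort)
  m <- as.matrix(items[item_cols])
  complete <- rowSums(is.na(m)) == 0
  fit <- logistic_fit(m[complete, , drop = FALSE],
                      as.integer(cohort$group[complete] == "SCLC"))
  keep <- item_cols
  tab <- data.frame(
    item = keep,
    n_events = fit$n_events[keep],
    odds_ratio = fit$odds_ratio[keep],
    lcl = fit$lcl[keep], ucl = fit$ucl[keep],
    p_value = fit$p_value[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_included = sum(complete),
                 n_excluded = sum(!complete), fit = fit),
            class = "multivariable_summary")
}

#' @export
print.multivariable_summary <- function(x, ...) {
  cat(sprintf("Multivariable logistic regression (n = %d, %d excluded)\n",
              x$n_included, x$n_excluded))
  tab <- x$table
  tab[, 3:6] <- round(tab[, 3:6], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-score SCLC risk table with Wilson intervals (Fig-1 style)
#'
#' For each attainable score the risk is the number of SCLC patients at that
#' score divided by all patients at that score, with a Wilson 95\% interval;
#' an empty stratum leaves the risk undefined (`NA`), never 0. Dichotomised
#' summaries report the fraction of scoreable patients in the low (0-1) and
#' high (3-max) strata.
#'
#' @param cohort validated cohort data.frame.
#' @param variant `"deltap"` (6-point, default) or `"dltap"` (5-point).
#' @return object of class `risk_table`: data.frame `table` (`score`,
#'   `n_total`, `n_sclc`, `risk`, `ci_lower`, `ci_upper`), `frac_low_01`,
#'   `frac_high_3plus`, `n_scoreable`, `n_excluded`, `variant`.
#' @export
risk_table <- function(cohort, variant = c("deltap", "dltap")) {
  variant <- match.arg(variant)
  cohort <- cohort[cohort$group %in% c("SCLC", "NT"), ]
  scored <- compute_deltap(derive_items(cohort))
  s <- scored[[variant]]
  ok <- !is.na(s)
  smax <- if (variant == "deltap") 6L else 5L
  tab <- do.call(rbind, lapply(0:smax, function(v) {
    idx <- ok & s == v
    n <- sum(idx)
    e <- sum(idx & cohort$group == "SCLC")
    ci <- wilson_ci(e, n)
    data.frame(score = v, n_total = n, n_sclc = e,
               risk = if (n > 0) e / n else NA_real_,
               ci_lower = ci[1], ci_upper = ci[2], row.names = NULL)
  }))
  n_scoreable <- sum(ok)
  structure(list(
    table = tab,
    frac_low_01 = sum(tab$n_total[tab$score <= 1]) / n_scoreable,
    frac_high_3plus = sum(tab$n_total[tab$score >= 3]) / n_scoreable,
    n_scoreable = n_scoreable, n_excluded = sum(!ok), variant = variant),
    class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("SCLC risk by %s score (n = %d scoreable, %d excluded)\n",
              toupper(x$variant), x$n_scoreable, x$n_excluded))
  tab <- x$table
  tab$risk_pct <- round(100 * tab$risk, 1)
  print(tab[, c("score", "n_total", "n_sclc", "risk_pct", "ci_lower", "ci_upper")],
        row.names = FALSE, digits = 3)
  cat(sprintf("  fraction scoring 0-1: %.1f%%; scoring 3+: %.1f%%\n",
              100 * x$frac_low_01, 100 * x$frac_high_3plus))
  invisible(x)
}

#' Individual item performance (Table-3 style)
#'
#' For each item in turn a patient is classified by whether the item value
#' matches the tumour status: a 1 in an SCLC patient or a 0 in a no-cancer
#' patient is correct; a 0 in SCLC or a 1 in no-cancer is incorrect.
#' Percentages are of the whole cohort. Patients with the item missing are
#' excluded for that item (count kept in `n_missing`).
#'
#' @param cohort validated cohort data.frame.
#' @return data.frame of class `item_performance`, one row per item:
#'   `item`, `correct1_sclc`, `correct0_nocancer`, `total_correct`,
#'   `incorrect0_sclc`, `incorrect1_nocancer`, `total_incorrect`,
#'   `n_missing`, plus `*_pct` columns (whole percentages of cohort n).
#' @export
item_performance <- function(cohort) {
  cohort <- cohort[cohort$group %in% c("SCLC", "NT"), ]
  items <- derive_items(cohort)
  sclc <- cohort$group == "SCLC"
  n <- nrow(cohort)
  out <- do.call(rbind, lapply(item_cols, function(col) {
    v <- items[[col]]
    ok <- !is.na(v)
    c1 <- sum(ok & sclc & v == 1)
    c0 <- sum(ok & !sclc & v == 0)
    i0 <- sum(ok & sclc & v == 0)
    i1 <- sum(ok & !sclc & v == 1)
    data.frame(item = col,
               correct1_sclc = c1, correct0_nocancer = c0, total_correct = c1 + c0,
               incorrect0_sclc = i0, incorrect1_nocancer = i1, total_incorrect = i0 + i1,
               n_missing = sum(!ok),
               correct1_pct = pct(c1, n), correct0_pct = pct(c0, n),
               total_correct_pct = pct(c1 + c0, n),
               incorrect0_pct = pct(i0, n), incorrect1_pct = pct(i1, n),
               total_incorrect_pct = pct(i0 + i1, n),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("item_performance", "data.frame")
  out
}

#' Contrast each item's accuracy against the other five pooled
#'
#' For each item, the correct/incorrect totals are tested against the pooled
#' correct/incorrect totals of the remaining five items with a two-sided
#' Fisher exact test, and the lowest-accuracy item is flagged. The
#' item-vs-pooled-rest contrast is this package's interpretation of "compared
#' to the other components" — it uses only the quantities the performance
#' table defines.
#'
#' @param perf `item_performance` data.frame.
#' @return data.frame with `item`, `accuracy`, `p_vs_others`, `flagged`
#'   (the minimum-accuracy item), sorted in the input item order.
#' @export
compare_items <- function(perf) {
  stopifnot(all(c("item", "total_correct", "total_incorrect") %in% names(perf)))
  perf <- perf[match(sort(perf$item), perf$item), ]  # canonical order, input-order invariant
  perf <- perf[match(intersect(item_cols, perf$item), perf$item), ]
  res <- do.call(rbind, lapply(seq_len(nrow(perf)), function(i) {
    a <- perf$total_correct[i]; b <- perf$total_incorrect[i]
    c_ <- sum(perf$total_correct[-i]); d <- sum(perf$total_incorrect[-i])
    p <- fisher_exact(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p_two_sided
    data.frame(item = perf$item[i], accuracy = a / (a + b), p_vs_others = p,
               stringsAsFactors = FALSE)
  }))
  res$flagged <- res$accuracy == min(res$accuracy)
  res
}
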