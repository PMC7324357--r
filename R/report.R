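#' Run the full DELTA-P validation analysis on a cohort
#'
#' One call produces every section of the validation report: the univariable
#' group comparison, the six-item multivariable logistic model, per-score
#' risk tables for both score variants, item performance with the
#' item-vs-rest contrasts, ROC/AUC for the 6-point and 5-point scores with
#' their paired comparison, subgroup AUCs by sex with the independent
#' comparison, per-patient screening schedules and the tumour-detection
#' summary — plus a manifest (input hash, package version, options) that
#' makes identical reruns byte-identical.
#'
#' Sections whose statistics are degenerate on the given cohort (e.g. a
#' single-sex cohort for the subgroup contrast) are included as structured
#' `"unavailable"` entries with the reason; errors are never swallowed into
#' fake numbers.
#'
#' @param cohort validated cohort data.frame.
#' @param high_grid HIGH-stratum screening grid, see [schedule_for_score()].
#' @return list of class `deltap_report`.
#' @export
run_validate <- function(cohort, high_grid = "offset") {
  cohort <- validate_cohort(as.data.frame(cohort), warn_followup = FALSE)
  scored <- score_cohort(cohort)
  safe <- function(expr) tryCatch(expr, error = function(e)
    list(unavailable = TRUE, reason = conditionMessage(e)))

  ok6 <- !is.na(scored$deltap)
  ok5 <- !is.na(scored$dltap)
  lab6 <- scored$group[ok6] == "SCLC"

  auc6 <- safe(auc_with_ci(scored$deltap[ok6], lab6))
  auc5 <- safe(auc_with_ci(scored$dltap[ok5], scored$group[ok5] == "SCLC"))
  both <- ok6 & ok5
  auc_compare <- safe(compare_auc_paired(scored$deltap[both], scored$dltap[both],
                                         scored$group[both] == "SCLC"))

  subgroup_auc <- lapply(c(M = "M", F = "F"), function(s) {
    idx <- ok6 & scored$sex == s
    safe(auc_with_ci(scored$deltap[idx], scored$group[idx] == "SCLC"))
  })
  sex_compare <- if (is.null(subgroup_auc$M$unavailable) &&
                     is.null(subgroup_auc$F$unavailable)) {
    compare_auc_independent(subgroup_auc$M, subgroup_auc$F)
  } else list(unavailable = TRUE, reason = "subgroup AUC unavailable")

  score_medians <- lapply(c(SCLC = "SCLC", NT = "NT"), function(g) {
    v <- scored$deltap[ok6 & scored$group == g]
    if (length(v) == 0) list(unavailable = TRUE, reason = "no scoreable patients")
    else suppressWarnings(median_with_ci(v))
  })

  schedules <- lapply(seq_len(nrow(scored)), function(i) {
    s <- scored$deltap[i]
    if (is.na(s)) return(list(patient_id = scored$patient_id[i],
                              unavailable = TRUE, reason = "score undefined"))
    sch <- schedule_for_score(s, high_grid = high_grid)
    list(patient_id = scored$patient_id[i], score = s,
         stratum = sch$score_stratum, scan_months = sch$scan_months)
  })

  manifest <- list(
    package = "deltap",
    version = as.character(utils::packageVersion("deltap")),
    n_patients = nrow(cohort),
    options = list(high_grid = high_grid),
    input_hash = fnv1a32(paste(utils::capture.output(
      utils::write.csv(as.data.frame(cohort), row.names = FALSE)), collapse = "\n"))
  )

  structure(list(
    manifest = manifest,
    univariable = safe(univariable_summary(cohort)),
    multivariable = safe(multivariable_summary(cohort)),
    risk_deltap = safe(risk_table(cohort, "deltap")),
    risk_dltap = safe(risk_table(cohort, "dltap")),
    item_performance = safe(item_performance(cohort)),
    item_contrasts = safe(compare_items(item_performance(cohort))),
    auc_deltap = auc6, auc_dltap = auc5, auc_comparison = auc_compare,
    subgroup_auc = subgroup_auc, sex_auc_comparison = sex_compare,
    score_medians = score_medians,
    roc_deltap = safe(roc_points(scored$deltap[ok6], lab6)),
    schedules = schedules,
    detection = safe(detection_summary(cohort)),
    n_unscoreable = sum(!ok6)
  ), class = "deltap_report")
}

#' @export
print.deltap_report <- function(x, ...) {
  cat("DELTA-P validation report —", x$manifest$n_patients, "patients\n\n")
  if (is.data.frame(x$univariable)) {
    cat("Univariable comparison (SCLC vs NT):\n")
    print(as.data.frame(x$univariable), row.names = FALSE, digits = 3)
  }
  cat("\n")
  if (inherits(x$multivariable, "multivariable_summary")) print(x$multivariable)
  cat("\n")
  if (inherits(x$risk_deltap, "risk_table")) print(x$risk_deltap)
  cat("\n")
  if (inherits(x$auc_deltap, "auc_result")) { cat("DELTA-P "); print(x$auc_deltap) }
  if (inherits(x$auc_dltap, "auc_result")) { cat("DLTA-P  "); print(x$auc_dltap) }
  if (inherits(x$auc_comparison, "auc_comparison")) print(x$auc_comparison)
  if (inherits(x$detection, "detection_summary")) { cat("\n"); print(x$detection) }
  invisible(x)
}

#' Write a validation report bundle to disk
#'
#' Emits `report.json` (full machine-readable bundle including the manifest),
#' plus human-oriented TSVs: `univariable.tsv`, `multivariable.tsv`,
#' `risk_deltap.tsv`, `risk_dltap.tsv`, `item_performance.tsv`, `roc.tsv`.
#' Output is deterministic: identical reports write byte-identical files.
#'
#' @param report a `deltap_report` from [run_validate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "deltap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- to_plain(report)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  tsv <- function(obj, name) {
    if (is.data.frame(obj))
      utils::write.table(obj, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  tsv(report$univariable, "univariable.tsv")
  if (inherits(report$multivariable, "multivariable_summary"))
    tsv(report$multivariable$table, "multivariable.tsv")
  if (inherits(report$risk_deltap, "risk_table"))
    tsv(report$risk_deltap$table, "risk_deltap.tsv")
  if (inherits(report$risk_dltap, "risk_table"))
    tsv(report$risk_dltap$table, "risk_dltap.tsv")
  tsv(report$item_performance, "item_performance.tsv")
  tsv(report$roc_deltap, "roc.tsv")
  invisible(dir)
}

# strip classes/attributes recursively so jsonlite serialises predictably
to_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass)))
  if (is.list(x)) return(lapply(unclass(x), to_plain))
  x
}
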