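#' PET/CT surveillance schedule for a DELTA-P score
#'
#' Every patient is scanned at LEMS diagnosis (month 0). Follow-up depends on
#' the score stratum:
#' \describe{
#'   \item{LOW (0-1)}{one repeat scan at 6 months.}
#'   \item{MID (2)}{repeat every six months for two years: 6, 12, 18, 24.}
#'   \item{HIGH (3-6)}{repeat at 3 months, then every six months for two
#'     years. The default grid reads "then every six months" from the
#'     month-3 scan (9, 15, 21, ending at the 24-month horizon); the
#'     alternative `high_grid = "aligned"` restarts the six-month cycle on
#'     the calendar grid (6, 12, 18, 24 after the month-3 scan).}
#' }
#'
#' @param score integer DELTA-P score in 0-6.
#' @param high_grid `"offset"` (default; scans 0,3,9,15,21) or `"aligned"`
#'   (scans 0,3,6,12,18,24) for the HIGH stratum.
#' @return object of class `screening_schedule`: `score_stratum`
#'   (`"LOW"`/`"MID"`/`"HIGH"`), `scan_months` (sorted, starting at 0),
#'   `horizon_months`.
#' @export
schedule_for_score <- function(score, high_grid = c("offset", "aligned")) {
  high_grid <- match.arg(high_grid)
  if (length(score) != 1 || is.na(score) || !score %in% 0:6)
    stop("score must be a single integer in 0-6")
  if (score <= 1) {
    stratum <- "LOW"; scans <- c(0, 6); horizon <- 6
  } else if (score == 2) {
    stratum <- "MID"; scans <- c(0, 6, 12, 18, 24); horizon <- 24
  } else {
    stratum <- "HIGH"
    scans <- if (high_grid == "offset") c(0, 3, 9, 15, 21) else c(0, 3, 6, 12, 18, 24)
    horizon <- 24
  }
  structure(list(score_stratum = stratum, scan_months = scans,
                 horizon_months = horizon),
            class = "screening_schedule")
}

#' @export
print.screening_schedule <- function(x, ...) {
  cat(sprintf("%s stratum: PET/CT at months %s (horizon %d months)\n",
              x$score_stratum, paste(x$scan_months, collapse = ", "),
              x$horizon_months))
  invisible(x)
}

#' Tumour-detection timing summary for a cohort
#'
#' Empirical fractions of SCLC patients whose tumour was confirmed within 6
#' and within 12 months of LEMS diagnosis, the median detection time, and
#' the late detections (beyond 6 months) with their DELTA-P scores.
#'
#' @param cohort validated cohort data.frame; SCLC patients should carry
#'   `tumour_detection_months`.
#' @return list of class `detection_summary`: `n_sclc`, `n_with_time`,
#'   `frac_within_6mo`, `frac_within_12mo`, `median_months`,
#'   `late_detections` (data.frame `patient_id`, `months`, `deltap`).
#' @export
detection_summary <- function(cohort) {
  sclc <- cohort[cohort$group == "SCLC", ]
  if (nrow(sclc) == 0) {
    warning("no SCLC patients: empty detection summary", call. = FALSE)
    return(structure(list(n_sclc = 0L, n_with_time = 0L,
                          frac_within_6mo = NA_real_, frac_within_12mo = NA_real_,
                          median_months = NA_real_,
                          late_detections = data.frame()),
                     class = "detection_summary"))
  }
  t <- sclc$tumour_detection_months
  ok <- !is.na(t)
  scores <- compute_deltap(derive_items(sclc))$deltap
  late <- ok & t > 6
  structure(list(
    n_sclc = nrow(sclc), n_with_time = sum(ok),
    frac_within_6mo = sum(t[ok] <= 6) / sum(ok),
    frac_within_12mo = sum(t[ok] <= 12) / sum(ok),
    median_months = stats::median(t[ok]),
    late_detections = data.frame(patient_id = sclc$patient_id[late],
                                 months = t[late], deltap = scores[late],
                                 stringsAsFactors = FALSE)),
    class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("Tumour detection (%d SCLC, %d with times): %.0f%% within 6 mo, %.0f%% within 12 mo; median %.1f mo\n",
              x$n_sclc, x$n_with_time, 100 * x$frac_within_6mo,
              100 * x$frac_within_12mo, x$median_months))
  if (nrow(x$late_detections) > 0) {
    cat("  late detections (> 6 mo):\n")
    print(x$late_detections, row.names = FALSE)
  }
  invisible(x)
}
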