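#' @title Cohort table schema
#' @description Column names and types of the per-patient cohort CSV. One row
#'   per patient; missing values written as `NA`. Tri-state clinical flags
#'   (`yes`/`no`/`NA`) record whether the feature was present within three
#'   months of LEMS symptom onset; the onset-window assessment itself is the
#'   data provider's responsibility.
#' @return data.frame with columns `column` and `type`.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("patient_id", "group", "sex", "age_years", "bulbar_weakness",
               "erectile_dysfunction", "weight_loss_ge5pct", "smoking_at_onset",
               "karnofsky", "karnofsky_lt70", "vgcc_titre_pM", "followup_months",
               "tumour_detection_months", "survival_months", "death_event"),
    type = c("character", "enum:SCLC|NT|UNKNOWN", "enum:M|F", "numeric",
             "tristate", "tristate", "tristate", "tristate",
             "integer 0-100", "tristate", "numeric>0", "numeric>=0",
             "numeric>=0", "numeric>=0", "0/1"),
    stringsAsFactors = FALSE
  )
}

tristate_cols <- c("bulbar_weakness", "erectile_dysfunction",
                   "weight_loss_ge5pct", "smoking_at_onset", "karnofsky_lt70")
numeric_cols <- c("age_years", "karnofsky", "vgcc_titre_pM", "followup_months",
                  "tumour_detection_months", "survival_months", "death_event")

#' Validate a cohort data frame
#'
#' Checks a per-patient table against the cohort schema: unique patient ids,
#' valid enumerations, non-negative times, agreement between `karnofsky` and
#' `karnofsky_lt70`, and the requirement that non-tumour (NT) patients carry
#' at least 36 months of cancer-free follow-up. Follow-up violations are
#' flagged (warning) rather than dropped, so the caller decides.
#'
#' @param cohort data.frame in the cohort schema (logical tri-states or
#'   `yes`/`no` strings both accepted).
#' @param warn_followup warn on NT patients with follow-up below 36 months.
#' @return the validated cohort (tri-states coerced to logical), invisibly
#'   classed `deltap_cohort`.
#' @seealso [read_cohort()], [cohort_schema()]
#' @export
validate_cohort <- function(cohort, warn_followup = TRUE) {
  stopifnot(is.data.frame(cohort))
  required <- cohort_schema()$column
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0) stop("no records: cohort table is empty")

  errs <- character(0)
  bad_cell <- function(rows, col, msg) {
    sprintf("row %d, column '%s': %s", rows, col, msg)
  }

  dup <- duplicated(cohort$patient_id)
  if (any(dup))
    errs <- c(errs, bad_cell(which(dup), "patient_id",
                             paste0("duplicate id '", cohort$patient_id[dup], "'")))

  bad <- !cohort$group %in% c("SCLC", "NT", "UNKNOWN")
  if (any(bad))
    errs <- c(errs, bad_cell(which(bad), "group",
                             paste0("invalid value '", cohort$group[bad],
                                    "' (expected SCLC/NT/UNKNOWN)")))
  bad <- !cohort$sex %in% c("M", "F")
  if (any(bad))
    errs <- c(errs, bad_cell(which(bad), "sex",
                             paste0("invalid value '", cohort$sex[bad], "' (expected M/F)")))

  for (col in tristate_cols) {
    v <- cohort[[col]]
    if (is.character(v)) {
      ok <- is.na(v) | v %in% c("yes", "no")
      if (any(!ok))
        errs <- c(errs, bad_cell(which(!ok), col,
                                 paste0("invalid value '", v[!ok], "' (expected yes/no/NA)")))
      cohort[[col]] <- ifelse(is.na(v), NA, v == "yes")
    } else if (!is.logical(v)) {
      errs <- c(errs, sprintf("column '%s': must be logical or yes/no/NA", col))
    }
  }

  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(cohort[[col]]))
    bad <- !is.na(v) & v < 0
    if (any(bad))
      errs <- c(errs, bad_cell(which(bad), col, paste0("negative value ", v[bad])))
    cohort[[col]] <- v
  }
  bad <- !is.na(cohort$karnofsky) &
    (cohort$karnofsky > 100 | cohort$karnofsky != round(cohort$karnofsky))
  if (any(bad))
    errs <- c(errs, bad_cell(which(bad), "karnofsky", "must be an integer in 0-100"))
  bad <- !is.na(cohort$death_event) & !cohort$death_event %in% c(0, 1)
  if (any(bad))
    errs <- c(errs, bad_cell(which(bad), "death_event", "must be 0 or 1"))

  # direct and derived Karnofsky entries must agree when both present
  both <- !is.na(cohort$karnofsky) & !is.na(cohort$karnofsky_lt70)
  contra <- both & ((cohort$karnofsky < 70) != cohort$karnofsky_lt70)
  if (any(contra))
    errs <- c(errs, sprintf(
      "row %d: patient '%s' has contradictory Karnofsky entries (karnofsky=%g, karnofsky_lt70=%s)",
      which(contra), cohort$patient_id[contra], cohort$karnofsky[contra],
      cohort$karnofsky_lt70[contra]))

  if (length(errs) > 0)
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)

  short <- cohort$group == "NT" &
    (is.na(cohort$followup_months) | cohort$followup_months < 36)
  if (warn_followup && any(short))
    warning("NT patients with < 36 months cancer-free follow-up (flagged, not dropped): ",
            paste(cohort$patient_id[short], collapse = ", "), call. = FALSE)

  class(cohort) <- c("deltap_cohort", "data.frame")
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a per-patient cohort table ([cohort_schema()] columns,
#' comma-separated, UTF-8, missing token `NA`). Extra columns are preserved
#' with a warning. All offending cells are reported in one error.
#'
#' @param path path to the CSV file.
#' @param quiet suppress the summary message.
#' @return validated cohort data.frame (class `deltap_cohort`).
#' @export
read_cohort <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("no records: cohort file '", path, "' has no data rows")
  extra <- setdiff(names(raw), cohort_schema()$column)
  if (length(extra) > 0)
    warning("unknown columns preserved unvalidated: ", paste(extra, collapse = ", "),
            call. = FALSE)
  cohort <- validate_cohort(raw)
  if (!quiet) {
    miss <- vapply(cohort[cohort_schema()$column], function(v) sum(is.na(v)), 0L)
    message(sprintf("read %d patients (%d SCLC, %d NT); columns with missing values: %s",
                    nrow(cohort), sum(cohort$group == "SCLC"), sum(cohort$group == "NT"),
                    if (any(miss > 0)) paste0(names(miss)[miss > 0], "=", miss[miss > 0],
                                              collapse = ", ") else "none"))
  }
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: logical tri-states are serialised as
#' `yes`/`no`, missing values as `NA`.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, cohort_schema()$column]
  for (col in tristate_cols)
    out[[col]] <- ifelse(is.na(out[[col]]), NA, ifelse(out[[col]], "yes", "no"))
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.deltap_cohort <- function(x, ...) {
  cat(sprintf("LEMS cohort: %d patients (%d SCLC, %d NT, %d unknown)\n",
              nrow(x), sum(x$group == "SCLC"), sum(x$group == "NT"),
              sum(x$group == "UNKNOWN")))
  NextMethod()
}
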