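#' Derive the six DELTA-P items from raw clinical fields
#'
#' The DELTA-P score sums six equally weighted binary items assessed within
#' three months of LEMS symptom onset:
#' \describe{
#'   \item{D}{bulbar/neck weakness}
#'   \item{E}{erectile dysfunction (males; females scored as not affected)}
#'   \item{L}{weight loss of 5\% or more}
#'   \item{T}{tobacco use at LEMS onset}
#'   \item{A}{age at onset 50 years or older (inclusive)}
#'   \item{P}{Karnofsky performance score below 70 (strict)}
#' }
#' Missing tri-state inputs propagate as missing items, except item E which is
#' forced to 0 for female patients regardless of the recorded value.
#'
#' @param cohort cohort data.frame (one or more rows) with the
#'   [cohort_schema()] clinical columns; tri-states logical or `yes`/`no`.
#' @return data.frame with columns `patient_id`, `D`, `E`, `L`, `T`, `A`, `P`
#'   (integer 0/1, `NA` = missing).
#' @export
derive_items <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  tri <- function(v) {
    if (is.character(v)) v <- ifelse(is.na(v), NA, v == "yes")
    as.integer(v)
  }
  if (any(is.na(cohort$age_years)))
    stop("age_years missing for patient(s): ",
         paste(cohort$patient_id[is.na(cohort$age_years)], collapse = ", "))

  k <- cohort$karnofsky
  klt <- tri(cohort$karnofsky_lt70)
  both <- !is.na(k) & !is.na(klt)
  contra <- both & (as.integer(k < 70) != klt)
  if (any(contra))
    stop("contradictory Karnofsky entries for patient(s): ",
         paste(cohort$patient_id[contra], collapse = ", "))
  p_item <- ifelse(!is.na(k), as.integer(k < 70), klt)

  e_item <- tri(cohort$erectile_dysfunction)
  e_item[cohort$sex == "F"] <- 0L  # females scored as not affected

  data.frame(
    patient_id = cohort$patient_id,
    D = tri(cohort$bulbar_weakness),
    E = e_item,
    L = tri(cohort$weight_loss_ge5pct),
    T = tri(cohort$smoking_at_onset),
    A = as.integer(cohort$age_years >= 50),
    P = p_item,
    stringsAsFactors = FALSE
  )
}

item_cols <- c("D", "E", "L", "T", "A", "P")

#' Compute DELTA-P (6-point) and DLTA-P (5-point) scores from derived items
#'
#' A score is the plain sum of its items and is left undefined (`NA`) when any
#' contributing item is missing — items are never imputed. The 5-point DLTA-P
#' variant drops item E (male erectile dysfunction) from both the sum and the
#' missingness accounting, so a patient missing only E still gets a DLTA-P.
#'
#' @param items data.frame from [derive_items()] (columns D,E,L,T,A,P).
#' @return data.frame with `patient_id` (if present), `deltap` (0-6 or `NA`),
#'   `dltap` (0-5 or `NA`), `n_missing_deltap`, `n_missing_dltap`.
#' @export
compute_deltap <- function(items) {
  stopifnot(all(item_cols %in% names(items)))
  m <- as.matrix(items[item_cols])
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !m %in% c(0L, 1L))) stop("items must be 0, 1 or NA")
  miss6 <- rowSums(is.na(m))
  miss5 <- rowSums(is.na(m[, setdiff(item_cols, "E"), drop = FALSE]))
  out <- data.frame(
    deltap = ifelse(miss6 == 0, rowSums(m), NA_integer_),
    dltap = ifelse(miss5 == 0, rowSums(m[, setdiff(item_cols, "E"), drop = FALSE]),
                   NA_integer_),
    n_missing_deltap = miss6,
    n_missing_dltap = miss5
  )
  if ("patient_id" %in% names(items))
    out <- cbind(items["patient_id"], out)
  out
}

#' Compute the 5-point DLTA-P variant alone
#'
#' Convenience wrapper returning only the E-free score; see [compute_deltap()].
#'
#' @inheritParams compute_deltap
#' @return data.frame with `patient_id` (if present), `dltap`, `n_missing_dltap`.
#' @export
compute_dltap <- function(items) {
  res <- compute_deltap(items)
  res[intersect(c("patient_id", "dltap", "n_missing_dltap"), names(res))]
}

#' Score a cohort on both DELTA-P variants
#'
#' @param cohort validated cohort data.frame.
#' @return the cohort with items and score columns appended.
#' @export
score_cohort <- function(cohort) {
  items <- derive_items(cohort)
  scores <- compute_deltap(items)
  cbind(as.data.frame(cohort), items[item_cols],
        scores[c("deltap", "dltap", "n_missing_deltap", "n_missing_dltap")])
}
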