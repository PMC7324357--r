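# Build a raw cohort whose derived items equal a given 0/1/NA item matrix.
# Inverts derive_items: ages 65/40 around the >=50 cut, Karnofsky 60/80
# around the <70 cut, tri-states from the binary items. Patients with E = 1
# must be male; unspecified sex defaults to M for E=1 and F otherwise.
make_item_cohort <- function(items, group, sex = NULL) {
  items <- as.matrix(items)
  colnames(items) <- c("D", "E", "L", "T", "A", "P")
  n <- nrow(items)
  if (is.null(sex)) sex <- ifelse(!is.na(items[, "E"]) & items[, "E"] == 1, "M", "F")
  stopifnot(all(sex[!is.na(items[, "E"]) & items[, "E"] == 1] == "M"))
  to_tri <- function(v) ifelse(is.na(v), NA, v == 1)
  k <- ifelse(is.na(items[, "P"]), NA_real_, ifelse(items[, "P"] == 1, 60, 80))
  data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    group = group,
    sex = sex,
    age_years = ifelse(is.na(items[, "A"]), 40, ifelse(items[, "A"] == 1, 65, 40)),
    bulbar_weakness = to_tri(items[, "D"]),
    erectile_dysfunction = ifelse(sex == "M", to_tri(items[, "E"]), NA),
    weight_loss_ge5pct = to_tri(items[, "L"]),
    smoking_at_onset = to_tri(items[, "T"]),
    karnofsky = k,
    karnofsky_lt70 = ifelse(is.na(k), NA, k < 70),
    vgcc_titre_pM = NA_real_,
    followup_months = ifelse(group == "NT", 48, NA_real_),
    tumour_detection_months = NA_real_,
    survival_months = NA_real_,
    death_event = NA_real_,
    stringsAsFactors = FALSE
  )
}

random_item_matrix <- function(n, p_missing = 0) {
  m <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  if (p_missing > 0) m[matrix(runif(n * 6) < p_missing, n, 6)] <- NA
  colnames(m) <- c("D", "E", "L", "T", "A", "P")
  m
}

random_cohort <- function(n = 40, p_missing = 0) {
  items <- random_item_matrix(n, p_missing)
  make_item_cohort(items, group = sample(c("SCLC", "NT"), n, replace = TRUE))
}

# independent combinatorial oracle for the two-sided Fisher p-value:
# enumerate every table with the observed margins, probability from
# binomial-coefficient products (no dhyper), sum those <= observed
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  tot <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / tot
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# rank-based empirical AUC used as a fast independent check
auc_rank <- function(scores, cases) {
  m <- as.numeric(sum(cases)); n <- as.numeric(sum(!cases))
  (sum(rank(scores)[cases]) - m * (m + 1) / 2) / (m * n)
}
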