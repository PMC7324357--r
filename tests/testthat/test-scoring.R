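test_that("items derive from raw fields with the documented cut-offs", {
  cohort <- data.frame(
    patient_id = c("a", "b", "c"),
    group = c("SCLC", "NT", "NT"),
    sex = c("F", "M", "M"),
    age_years = c(62, 30, 49.9),
    bulbar_weakness = c(TRUE, FALSE, FALSE),
    erectile_dysfunction = c(TRUE, FALSE, FALSE),  # female entry must be overridden
    weight_loss_ge5pct = c(TRUE, FALSE, FALSE),
    smoking_at_onset = c(TRUE, FALSE, FALSE),
    karnofsky = c(60, 90, 70),
    karnofsky_lt70 = c(NA, NA, NA),
    vgcc_titre_pM = NA_real_, followup_months = c(NA, 48, 48),
    tumour_detection_months = NA_real_, survival_months = NA_real_,
    death_event = NA_real_, stringsAsFactors = FALSE)
  it <- derive_items(cohort)
  # female, 62, bulbar/weight/smoker yes, Karnofsky 60: everything except E
  expect_equal(unlist(it[1, c("D", "E", "L", "T", "A", "P")]),
               c(D = 1, E = 0, L = 1, T = 1, A = 1, P = 1))
  # all-negative male
  expect_equal(sum(unlist(it[2, c("D", "E", "L", "T", "A", "P")])), 0)
  # boundaries: age 49.9 is below the inclusive >=50 cut, Karnofsky 70 is not <70
  expect_equal(it$A[3], 0L)
  expect_equal(it$P[3], 0L)
})

test_that("contradictory Karnofsky entries raise an error naming the patient", {
  cohort <- make_item_cohort(matrix(0, 1, 6), "NT")
  cohort$karnofsky <- 80
  cohort$karnofsky_lt70 <- TRUE
  expect_error(derive_items(cohort), "T0001")
  expect_error(validate_cohort(cohort), "contradictory")
})

test_that("scores sum the items, with missingness never imputed", {
  m <- rbind(rep(1, 6),                 # male, all items
             rep(0, 6),                 # all negative
             c(1, NA, 1, 1, 1, 1),      # female pattern: E overridden to 0
             c(0, 1, 0, 0, 0, 0),       # E-only male
             c(NA, NA, NA, NA, 1, NA))  # mostly missing
  cohort <- make_item_cohort(m, "SCLC",
                             sex = c("M", "M", "F", "M", "F"))
  sc <- compute_deltap(derive_items(cohort))
  expect_equal(sc$deltap, c(6L, 0L, 5L, 1L, NA))
  expect_equal(sc$dltap, c(5L, 0L, 5L, 0L, NA))
  expect_equal(sc$n_missing_deltap, c(0, 0, 0, 0, 4))
  # DLTA-P variant drops E from missingness accounting too
  expect_equal(sc$n_missing_dltap[5], 4)
  only_e_missing <- make_item_cohort(matrix(c(1, NA, 1, 0, 1, 0), 1), "SCLC", sex = "M")
  sc2 <- compute_deltap(derive_items(only_e_missing))
  expect_true(is.na(sc2$deltap))
  expect_equal(sc2$dltap, 3L)
  expect_equal(compute_dltap(derive_items(only_e_missing))$dltap, 3L)
})

test_that("score identities hold on randomized cohorts", {
  set.seed(101)
  for (rep in 1:5) {
    cohort <- random_cohort(60)
    items <- derive_items(cohort)
    sc <- compute_deltap(items)
    expect_true(all(sc$deltap >= 0 & sc$deltap <= 6))
    expect_equal(sc$deltap - sc$dltap, items$E)
    expect_true(all(sc$deltap[cohort$sex == "F"] <= 5))
    # permutation invariance and idempotence
    perm <- sample(nrow(cohort))
    sc_perm <- compute_deltap(derive_items(cohort[perm, ]))
    expect_equal(sc_perm$deltap, sc$deltap[perm])
    expect_equal(compute_deltap(items), sc)
  }
})
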