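test_that("the generator is fully seed-determined", {
  cfg <- cohort_config(seed = 5)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- cohort_config(seed = 6)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("generated cohorts satisfy the record invariants", {
  for (s in 1:5) {
    co <- simulate_cohort(cohort_config(seed = s))
    expect_s3_class(validate_cohort(co), "deltap_cohort")
    expect_true(all(co$followup_months[co$group == "NT"] >= 36))
    it <- derive_items(co)
    expect_true(all(it$E[co$sex == "F"] == 0))
    expect_true(all(!is.na(co$tumour_detection_months[co$group == "SCLC"])))
  }
})

test_that("empirical item frequencies recover the configuration at n = 50,000", {
  big <- simulate_cohort(cohort_config(n_total = 50000, seed = 7))
  it <- derive_items(big)
  sclc <- big$group == "SCLC"
  male <- big$sex == "M"
  pr <- default_item_probs()
  for (col in c("D", "L", "T", "A", "P")) {
    expect_lt(abs(mean(it[[col]][sclc]) - pr[col, "SCLC"]), 0.01)
    expect_lt(abs(mean(it[[col]][!sclc]) - pr[col, "NT"]), 0.01)
  }
  expect_lt(abs(mean(it$E[sclc & male]) - pr["E", "SCLC"]), 0.015)
  expect_lt(abs(mean(it$E[!sclc & male]) - pr["E", "NT"]), 0.015)
  expect_lt(abs(mean(sclc) - 44 / 87), 0.01)
})

test_that("SCLC counts are centred on 44 of 87 across seeds", {
  counts <- vapply(1:30, function(s)
    sum(simulate_cohort(cohort_config(seed = 100 + s))$group == "SCLC"), 0)
  expect_gt(mean(counts), 44 - 3)
  expect_lt(mean(counts), 44 + 3)
})

test_that("titres and survival reflect the configured medians", {
  big <- simulate_cohort(cohort_config(n_total = 20000, seed = 8))
  sclc <- big$group == "SCLC"
  expect_equal(median(big$vgcc_titre_pM[sclc], na.rm = TRUE), 448, tolerance = 0.1)
  expect_equal(median(big$vgcc_titre_pM[!sclc], na.rm = TRUE), 209, tolerance = 0.1)
  sv <- survival_compare(big$survival_months, big$death_event, big$group)
  expect_equal(unname(sv$medians["SCLC"]), 15.6, tolerance = 0.1)
  expect_equal(unname(sv$medians["NT"]), 50, tolerance = 0.1)
})

test_that("the latent-severity copula mode induces positive item dependence", {
  expect_error(cohort_config(rho = 1.2), "rho")
  big0 <- simulate_cohort(cohort_config(n_total = 20000, rho = 0, seed = 9))
  big5 <- simulate_cohort(cohort_config(n_total = 20000, rho = 0.5, seed = 9))
  cor0 <- cor(derive_items(big0)$D, derive_items(big0)$L)
  cor5 <- cor(derive_items(big5)$D, derive_items(big5)$L)
  expect_gt(cor5, cor0 + 0.05)
  # marginal frequencies are preserved under dependence
  pr <- default_item_probs()
  sclc <- big5$group == "SCLC"
  expect_lt(abs(mean(derive_items(big5)$D[sclc]) - pr["D", "SCLC"]), 0.015)
})

test_that("the deterministic fixture reproduces the published marginals", {
  fx <- fixture_table1()
  expect_identical(fx, fixture_table1())
  expect_equal(nrow(fx), 87)
  sclc <- fx$group == "SCLC"
  expect_equal(sum(sclc), 44)
  it <- derive_items(fx)
  expect_equal(colSums(it[sclc, c("D", "E", "L", "T", "A", "P")]),
               c(D = 24, E = 9, L = 27, T = 29, A = 40, P = 23))
  expect_equal(colSums(it[!sclc, c("D", "E", "L", "T", "A", "P")]),
               c(D = 11, E = 8, L = 8, T = 7, A = 30, P = 10))
  expect_equal(sum(fx$sex[sclc] == "M"), 16)
  expect_equal(sum(fx$sex[!sclc] == "M"), 17)
  expect_equal(sum(!is.na(fx$vgcc_titre_pM[sclc])), 42)
  expect_equal(sum(!is.na(fx$vgcc_titre_pM[!sclc])), 36)
  # smoking contrast is overwhelming, as published
  expect_lt(fisher_exact(matrix(c(29, 15, 7, 36), 2, byrow = TRUE))$p_two_sided,
            1e-4)
})

test_that("analytic AUC of the default generator matches large-sample empirical AUC", {
  pr <- default_item_probs()
  # cohort-level item probabilities: E is diluted by the female fraction
  male_frac <- c(SCLC = 16 / 44, NT = 17 / 43)
  p_case <- pr[, "SCLC"]; p_case["E"] <- p_case["E"] * male_frac["SCLC"]
  p_ctrl <- pr[, "NT"]; p_ctrl["E"] <- p_ctrl["E"] * male_frac["NT"]
  ana <- analytic_auc_from_item_probs(p_case, p_ctrl)$auc
  big <- simulate_cohort(cohort_config(n_total = 50000, seed = 10))
  sc <- compute_deltap(derive_items(big))
  emp <- auc_rank(sc$deltap, big$group == "SCLC")
  expect_lt(abs(emp - ana), 0.01)
})
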