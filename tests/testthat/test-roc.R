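test_that("operating points come from exhaustive threshold counting", {
  pts <- roc_points(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pts$threshold, c(Inf, 3, 2, 1))
  expect_equal(pts$sensitivity, c(0, 0.5, 1, 1))
  expect_equal(pts$specificity, c(1, 0.5, 0.5, 0))
  expect_equal(pts$tp + pts$fn, rep(2, 4))
  expect_equal(pts$tn + pts$fp, rep(2, 4))
  # perfectly separated scores pass through sens = 1, spec = 1
  sep <- roc_points(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
  # constant scores give the diagonal corners only
  flat <- roc_points(rep(3, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(flat$sensitivity, c(0, 1))
  expect_equal(flat$specificity, c(1, 0))
  expect_error(roc_points(1:4, rep(TRUE, 4)), "cases and controls")
})

test_that("AUC is the tie-credited pairwise estimator", {
  expect_equal(auc_with_ci(c(2, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.625)
  expect_equal(auc_with_ci(c(4, 5, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
})

test_that("pairwise AUC equals the trapezoidal area under the ROC curve", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- sample(0:6, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    pts <- roc_points(scores, labels)
    fpr <- 1 - pts$specificity
    trap <- sum(diff(fpr) * (head(pts$sensitivity, -1) + tail(pts$sensitivity, -1)) / 2)
    expect_equal(auc_with_ci(scores, labels)$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC of negated scores is the complement", {
  set.seed(72)
  scores <- sample(0:6, 100, replace = TRUE)
  labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 98, replace = TRUE))
  expect_equal(auc_with_ci(scores, labels)$auc +
                 auc_with_ci(-scores, labels)$auc, 1)
})

test_that("DeLong variance and CI match pROC", {
  skip_if_not_installed("pROC")
  set.seed(73)
  for (i in 1:10) {
    scores <- sample(0:6, 87, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 85, replace = TRUE))
    res <- auc_with_ci(scores, labels)
    roc <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                     direction = "<")
    expect_equal(res$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
    expect_equal(res$se^2, as.numeric(pROC::var(roc, method = "delong")),
                 tolerance = 1e-9)
  }
})

test_that("shuffled labels give a null AUC near 0.5", {
  set.seed(74)
  inside <- 0
  for (s in 1:20) {
    scores <- sample(0:6, 500, replace = TRUE)
    labels <- sample(rep(c(TRUE, FALSE), 250))
    a <- auc_with_ci(scores, labels)$auc
    inside <- inside + (a >= 0.42 && a <= 0.58)
  }
  expect_gte(inside, 19)
})

test_that("paired DeLong comparison is null for identical scores and matches pROC", {
  scores <- c(1, 3, 5, 0, 2, 4, 6, 1, 2, 3)
  labels <- rep(c(TRUE, FALSE), 5)
  res <- compare_auc_paired(scores, scores, labels)
  expect_equal(res$z, 0)
  expect_equal(res$p_two_sided, 1)
  expect_error(compare_auc_paired(1:4, 1:5, rep(c(TRUE, FALSE), c(2, 3))),
               "same patients")

  skip_if_not_installed("pROC")
  set.seed(75)
  a <- sample(0:6, 87, replace = TRUE)
  b <- pmax(0, a + sample(-1:1, 87, replace = TRUE))
  labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 85, replace = TRUE))
  res <- compare_auc_paired(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-9)
})

test_that("independent comparison reproduces the subgroup contrast arithmetic", {
  # AUC 85.3% (CI half-width 13.65% -> SE 6.96%) vs 82.01% (SE 5.66%)
  res <- compare_auc_independent(list(auc = 0.853, se = 0.1365 / qnorm(0.975)),
                                 list(auc = 0.8201, se = 0.111 / qnorm(0.975)))
  expect_equal(res$p_two_sided, 0.714, tolerance = 0.005)
  expect_equal(round(res$p_two_sided, 2), 0.71)
  # symmetric in argument order; null when equal
  res_swap <- compare_auc_independent(list(auc = 0.8201, se = 0.0566),
                                      list(auc = 0.853, se = 0.0696))
  expect_equal(res_swap$p_two_sided,
               compare_auc_independent(list(auc = 0.853, se = 0.0696),
                                       list(auc = 0.8201, se = 0.0566))$p_two_sided)
  eqres <- compare_auc_independent(list(auc = 0.8, se = 0.05),
                                   list(auc = 0.8, se = 0.05))
  expect_equal(eqres$p_two_sided, 1)
  # paired comparison reduces to the independent one when the covariance is zero
  z_indep <- (0.9 - 0.8) / sqrt(0.03^2 + 0.04^2)
  expect_equal(compare_auc_independent(list(auc = 0.9, se = 0.03),
                                       list(auc = 0.8, se = 0.04))$z, z_indep)
})

test_that("analytic convolution AUC has the closed-form endpoints", {
  expect_equal(analytic_auc_from_item_probs(rep(0.3, 6), rep(0.3, 6))$auc, 0.5)
  expect_equal(analytic_auc_from_item_probs(rep(1, 6), rep(0, 6))$auc, 1)
  res <- analytic_auc_from_item_probs(rep(0.5, 6), rep(0.5, 6))
  expect_equal(sum(res$dist_case), 1)
  expect_equal(res$dist_case, dbinom(0:6, 6, 0.5))
})

test_that("empirical AUC converges to the analytic convolution value", {
  pr <- default_item_probs()
  ana <- analytic_auc_from_item_probs(pr[, "SCLC"], pr[, "NT"])
  set.seed(76)
  n <- 50000
  s_case <- rowSums(matrix(runif(n * 6), n, 6) < rep(pr[, "SCLC"], each = n))
  s_ctrl <- rowSums(matrix(runif(n * 6), n, 6) < rep(pr[, "NT"], each = n))
  emp <- auc_rank(c(s_case, s_ctrl), rep(c(TRUE, FALSE), each = n))
  expect_lt(abs(emp - ana$auc), 0.01)
})
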