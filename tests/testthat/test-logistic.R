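test_that("intercept-only fit recovers the event prevalence", {
  y <- c(rep(1, 13), rep(0, 27))
  fit <- logistic_fit(matrix(numeric(0), nrow = 40, ncol = 0), y)
  expect_equal(unique(round(fit$fitted, 10)), 13 / 40)
})

test_that("single binary covariate gives the contingency cross-product OR", {
  x <- matrix(c(rep(1, 29), rep(0, 15), rep(1, 7), rep(0, 36)), ncol = 1,
              dimnames = list(NULL, "T"))
  y <- c(rep(1, 44), rep(0, 43))
  fit <- logistic_fit(x, y)
  expect_equal(unname(fit$odds_ratio["T"]), 1044 / 105, tolerance = 1e-6)
  expect_equal(unname(fit$n_events["T"]), 36L)
})

test_that("single-covariate OR equals the cross-product ratio on random tables", {
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    x <- matrix(rep(c(1, 0, 1, 0), tab), ncol = 1, dimnames = list(NULL, "v"))
    y <- rep(c(1, 1, 0, 0), tab)
    fit <- logistic_fit(x, y)
    expect_equal(unname(fit$odds_ratio["v"]),
                 tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-6)
  }
})

test_that("coefficients, Wald SEs and p-values match stats::glm", {
  set.seed(42)
  x <- matrix(rbinom(87 * 4, 1, 0.4), 87, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- rbinom(87, 1, plogis(-0.5 + x %*% c(1, 0.5, -0.7, 0)))
  fit <- logistic_fit(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$p_value[-1]),
               unname(summary(ref)$coefficients[-1, 4]), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$lcl <= fit$odds_ratio & fit$odds_ratio <= fit$ucl))
})

test_that("degenerate designs raise structured errors", {
  y <- rep(c(0, 1), 20)
  expect_error(logistic_fit(matrix(1, 40, 1, dimnames = list(NULL, "flat")), y),
               "flat")
  expect_error(logistic_fit(matrix(0.5, 40, 1), rep(1, 40)), "at least one")
  # complete separation: covariate equals outcome
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "mirror"))
  expect_error(logistic_fit(x, y), "separation.*mirror")
})

test_that("fit recovers generator log-odds on a large simulated cohort", {
  # conditionally independent items make the SCLC posterior exactly logistic
  # with coefficients log[p1(1-p0)/(p0(1-p1))]; check recovery at large n
  big <- simulate_cohort(cohort_config(n_total = 20000, seed = 11))
  items <- derive_items(big)
  males <- big$sex == "M"
  m <- as.matrix(items[males, c("D", "E", "L", "T", "A", "P")])
  fit <- logistic_fit(m, as.integer(big$group[males] == "SCLC"))
  pr <- default_item_probs()
  implied <- log(pr[, "SCLC"] * (1 - pr[, "NT"]) / (pr[, "NT"] * (1 - pr[, "SCLC"])))
  expect_equal(unname(fit$coefficients[c("D", "E", "L", "T", "A", "P")]),
               unname(implied), tolerance = 0.15)
})
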