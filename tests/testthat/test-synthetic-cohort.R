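# Synthetic open-cohort generator: structural invariants, calibration of the
# exposure marginals, the confounding knob, and the ground-truth oracle.

test_that("generated cohort satisfies the person-year invariants and is deterministic", {
  cfg <- cohort_config(n_persons = 1500, seed = 42)
  tab <- generate_cohort(cfg)
  expect_true(validate_person_year_table(tab))
  # mortality conservation: each person contributes 0 or 1 death
  expect_true(all(tapply(tab$death, tab$person_id, sum) <= 1))
  # staggered open cohort: multiple entry years, censoring at end of study
  entry <- tapply(tab$year, tab$person_id, min)
  expect_gt(length(unique(entry)), 10)
  last <- tapply(tab$year, tab$person_id, max)
  died <- tapply(tab$death, tab$person_id, sum)
  expect_true(all(last[died == 0] == cfg$year_range[2]))
  # determinism: identical config + seed give identical tables
  expect_identical(tab, generate_cohort(cfg))
  # a different seed gives a different table
  expect_false(identical(tab, generate_cohort(cohort_config(n_persons = 1500, seed = 43))))
})

test_that("exposure marginals and correlations match the configured values", {
  tab <- small_cohort(n = 20000, seed = 3)
  cfg <- attr(tab, "config")
  expect_lt(abs(mean(tab$pm25) - 8.18), 0.1)
  expect_lt(abs(mean(tab$no2) - 19.80), 0.3)
  expect_lt(abs(mean(tab$o3) - 41.94), 0.5)
  C <- cor(tab[, c("pm25", "no2", "o3")])
  target <- cfg$exposure_corr[c("pm25", "no2", "o3"), c("pm25", "no2", "o3")]
  expect_true(all(abs(C - target)[upper.tri(C)] < 0.05))
  expect_true(all(target[upper.tri(target)] >= 0.11 &
                  target[upper.tri(target)] <= 0.59))
})

test_that("confounding knob: zero loadings give uncorrelated exposures and covariates", {
  tab <- generate_cohort(cohort_config(n_persons = 14000, seed = 5,
                                       confounding_strength = c(income = 0)))
  expect_gt(nrow(tab), 1e5)
  for (v in c("income", "poverty", "density", "smoking")) {
    expect_lt(abs(cor(tab$pm25, tab[[v]])), 0.02)
  }
  # default loadings do induce exposure-confounder correlation
  tab2 <- small_cohort(n = 5000, seed = 5)
  expect_gt(abs(cor(tab2$pm25, tab2$smoking)), 0.04)
})

test_that("true_marginal_rd returns the configured effect and rejects unknown names", {
  cfg <- cohort_config(n_persons = 10)
  expect_equal(true_marginal_rd(cfg, "pm25"), 7.3e-4)
  expect_equal(true_marginal_rd(cfg, "no2"), 3e-5)
  expect_equal(true_marginal_rd(cfg, "o3"), 8.1e-4)
  cfg0 <- cohort_config(n_persons = 10, true_rd = c(pm25 = 0, no2 = 0, o3 = 0))
  expect_equal(true_marginal_rd(cfg0, "pm25"), 0)
  expect_error(true_marginal_rd(cfg, "lead"), "unknown exposure")
})

test_that("ground truth is recovered by unweighted regression on a confounder-free cohort", {
  # brute-force simulation oracle: no confounding, so a plain linear
  # regression of death on the exposures is consistent for the true rd
  cfg <- cohort_config(n_persons = 40000, seed = 77,
                       confounding_strength = c(income = 0))
  tab <- generate_cohort(cfg)
  fit <- lm(death ~ pm25 + no2 + o3 + I(scale(age)) + I(scale(income)) +
              I(scale(poverty)) + I(scale(density)) + I(scale(smoking)), data = tab)
  est <- coef(fit)["pm25"]
  se <- sqrt(diag(vcov(fit)))["pm25"]
  expect_lt(abs(est - true_marginal_rd(cfg, "pm25")), 3 * se)
  est_o3 <- coef(fit)["o3"]
  se_o3 <- sqrt(diag(vcov(fit)))["o3"]
  expect_lt(abs(est_o3 - true_marginal_rd(cfg, "o3")), 3 * se_o3)
  # clipping affects well under 1% of rows
  expect_lt(attr(tab, "clip_fraction"), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_persons = 0), "positive")
  expect_error(cohort_config(baseline_annual_risk = 1.2), "0, 1")
  bad <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3, 3,
                dimnames = rep(list(c("pm25", "no2", "o3")), 2))
  expect_error(cohort_config(exposure_corr = bad), "positive definite")
  asym <- matrix(c(1, 0.2, 0.4, 0.3, 1, 0.2, 0.3, 0.2, 1), 3, 3,
                 dimnames = rep(list(c("pm25", "no2", "o3")), 2))
  expect_error(cohort_config(exposure_corr = asym), "symmetric")
})
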