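# Balance diagnostics: weighted correlation oracle and the balance report's
# internal consistency and behaviour under weighting.

test_that("weighted correlation reduces to Pearson with equal weights and hits 1 at c = x", {
  set.seed(61)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50)
  expect_equal(weighted_correlation(x, y, rep(1, 50)), cor(x, y), tolerance = 1e-12)
  expect_equal(weighted_correlation(x, y, rep(2.5, 50)), cor(x, y), tolerance = 1e-12)
  expect_equal(weighted_correlation(x, x, runif(50, 0.5, 2)), 1, tolerance = 1e-12)
  expect_error(weighted_correlation(x, y, rep(-1, 50)), "positive")
  expect_error(weighted_correlation(x, rep(3, 50), rep(1, 50)), "variance")
  expect_error(weighted_correlation(x, y[1:10], rep(1, 50)), "equal lengths")
})

test_that("5-point hand example matches a direct weighted-moment computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  w <- c(1, 1, 2, 2, 4)
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  cov_w <- sum(w * (x - mx) * (y - my)) / sw
  r_hand <- cov_w / sqrt(sum(w * (x - mx)^2) / sw * sum(w * (y - my)^2) / sw)
  expect_equal(weighted_correlation(x, y, w), r_hand, tolerance = 1e-12)
})

test_that("balance report is internally consistent and unit weights collapse columns", {
  tab <- small_cohort(n = 1000, seed = 62)
  covs <- c("income", "poverty", "smoking", "education")
  rep1 <- balance_report(tab, rep(1, nrow(tab)), "pm25", covs)
  expect_equal(rep1$abs_cor_unweighted, rep1$abs_cor_weighted, tolerance = 1e-12)
  expect_equal(attr(rep1, "avg_unweighted"), mean(rep1$abs_cor_unweighted))
  expect_equal(attr(rep1, "avg_weighted"), mean(rep1$abs_cor_weighted))
  expect_true(all(rep1$abs_cor_unweighted >= 0 & rep1$abs_cor_unweighted <= 1))
})

test_that("GPS weighting halves the average absolute correlation; independence gives ~0", {
  tab <- small_cohort(n = 14000, seed = 63)
  expect_gt(nrow(tab), 1e5)
  ws <- gps_weights(tab, "pm25", default_ps_spec())
  covs <- c("income", "poverty", "smoking", "education")
  rep_w <- balance_report(tab, ws, "pm25", covs)
  expect_lt(attr(rep_w, "avg_weighted"), 0.5 * attr(rep_w, "avg_unweighted"))
  # comparison mode: a cubic-PS weight set reported side by side
  ws3 <- gps_weights(tab, "pm25", default_ps_spec(degree = 3))
  rep_cmp <- balance_report(tab, ws, "pm25", covs, weights2 = ws3)
  expect_false(is.null(attr(rep_cmp, "avg_weighted2")))
  expect_lt(attr(rep_cmp, "avg_weighted2"), attr(rep_cmp, "avg_unweighted"))

  # exposure independent of all covariates: both averages near zero
  tab0 <- generate_cohort(cohort_config(n_persons = 14000, seed = 64,
                                        confounding_strength = c(income = 0)))
  ws0 <- gps_weights(tab0, "pm25", default_ps_spec())
  rep0 <- balance_report(tab0, ws0, "pm25", covs)
  expect_lt(attr(rep0, "avg_unweighted"), 0.02)
  expect_lt(attr(rep0, "avg_weighted"), 0.02)
})

test_that("true inverse-density weights remove correlation almost entirely", {
  # with the generator's own confounder index known, the exact stabilized
  # weight is the ratio of the true marginal to the true conditional density
  # single-year cohort: 1e5 independent rows, so follow-up truncation plays
  # no role and the property is tested on the exposure model alone
  tab <- generate_cohort(cohort_config(n_persons = 1e5, seed = 65,
                                       year_range = c(2016, 2016)))
  cfg <- attr(tab, "config")
  cs <- cfg$confounding_strength
  z <- function(v) (v - mean(v)) / sd(v)
  h <- cs[["income"]] * z(tab$income) + cs[["poverty"]] * z(tab$poverty) +
    cs[["smoking"]] * z(tab$smoking) + cs[["education"]] * z(tab$education) +
    cs[["income_sq"]] * (z(tab$income)^2 - 1) / sqrt(2)
  s <- cfg$exposure_sds[["pm25"]]
  vh <- mean((h - mean(h))^2)
  mu_c <- cfg$exposure_means[["pm25"]] + s * h
  sd_c <- s * sqrt(1 - vh)
  w_true <- dnorm(tab$pm25, mean(tab$pm25), sd(tab$pm25)) /
    dnorm(tab$pm25, mu_c, sd_c)
  covs <- c("income", "poverty", "smoking", "education")
  rep_t <- balance_report(tab, w_true, "pm25", covs)
  expect_lt(max(rep_t$abs_cor_weighted), 0.02)
})
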