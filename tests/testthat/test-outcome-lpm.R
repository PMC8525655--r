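# Weighted linear probability model: normal-equations oracle, sandwich
# behaviour in the homoscedastic limit, fixed-effects meta-analysis closed
# forms, split-and-pool consistency, and the single-pollutant comparison.

test_that("unweighted symmetric design gives beta 0 and intercept 0.5", {
  tab <- data.frame(person_id = 1:4, year = 2000,
                    pm25 = c(0.5, 0.5, 1.5, 1.5), death = c(0, 1, 0, 1))
  sp <- outcome_spec("pm25")
  fit <- fit_weighted_lpm(tab, rep(1, 4), sp)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.5, tolerance = 1e-12)
  expect_equal(fit$person_years, 4)
})

test_that("weighted fit solves the weighted normal equations", {
  tab <- data.frame(person_id = 1:6, year = 2000,
                    pm25 = c(1, 2, 3, 4, 5, 6),
                    income = c(2, 1, 4, 3, 6, 5),
                    death = c(0, 0, 1, 0, 1, 1))
  w <- c(0.5, 1, 2, 1.5, 3, 0.25)
  sp <- outcome_spec("pm25", continuous = "income", cubic_terms = character())
  fit <- fit_weighted_lpm(tab, w, sp)
  # independent matrix-inversion oracle on the same design
  z <- (tab$income - mean(tab$income)) / sd(tab$income)
  X <- cbind(1, tab$pm25, z)
  b <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% tab$death)
  expect_equal(fit$beta, b[2], tolerance = 1e-10)
  expect_error(fit_weighted_lpm(tab, c(w[-6], 0), sp), "positive")
})

test_that("HC1 robust SE approaches the classical SE in the homoscedastic limit", {
  set.seed(41)
  n <- 1e5
  tab <- data.frame(person_id = seq_len(n), year = 2000,
                    pm25 = rnorm(n, 8, 2))
  tab$death <- 0.2 + 0.01 * tab$pm25 + rnorm(n, sd = 0.1)  # homoscedastic
  fit <- fit_weighted_lpm(tab, rep(1, n), outcome_spec("pm25"))
  expect_lt(abs(fit$robust_se / fit$classical_se - 1), 0.05)
})

test_that("person-clustered sandwich handles repeated rows per person", {
  tab <- small_cohort(n = 1500, seed = 42)
  sp <- default_outcome_spec()
  f_h <- fit_weighted_lpm(tab, NULL, sp, cluster = "none")
  f_c <- fit_weighted_lpm(tab, NULL, sp, cluster = "person")
  expect_equal(f_h$beta, f_c$beta)           # same point estimate
  expect_gt(f_c$robust_se, 0)
  expect_lt(abs(log(f_c$robust_se / f_h$robust_se)), log(1.5))
})

test_that("fixed-effects meta-analysis matches its closed forms", {
  mk <- function(b, se) list(beta = b, robust_se = se, n_rows = 10, n_persons = 5)
  # G identical results pool to (b, se/sqrt(G))
  m <- meta_fixed(rep(list(mk(2.5, 0.8)), 7))
  expect_equal(m$pooled_beta, 2.5, tolerance = 1e-12)
  expect_equal(m$pooled_se, 0.8 / sqrt(7), tolerance = 1e-12)
  # equal-SE pair averages
  m2 <- meta_fixed(list(mk(1, 1), mk(3, 1)))
  expect_equal(m2$pooled_beta, 2)
  expect_equal(m2$pooled_se, sqrt(0.5))
  # random set against the direct inverse-variance formula
  set.seed(43)
  b <- rnorm(5); se <- runif(5, 0.5, 2)
  m3 <- meta_fixed(Map(mk, b, se))
  wi <- 1 / se^2
  expect_equal(m3$pooled_beta, sum(wi * b) / sum(wi), tolerance = 1e-12)
  expect_equal(m3$pooled_se, sqrt(1 / sum(wi)), tolerance = 1e-12)
  # invariants: pooled SE below the smallest group SE, beta inside the range
  expect_lt(m3$pooled_se, min(se))
  expect_gte(m3$pooled_beta, min(b))
  expect_lte(m3$pooled_beta, max(b))
  expect_error(meta_fixed(list()), "empty")
})

test_that("split-and-fit: G = 1 equals the single fit, same seed reproduces, G = 10 consistent", {
  tab <- small_cohort(n = 6000, seed = 44)
  sp <- default_outcome_spec()
  ws <- gps_weights(tab, "pm25", default_ps_spec())
  full <- fit_weighted_lpm(tab, ws, sp)
  m1 <- split_and_fit(tab, ws, sp, n_groups = 1, seed = 7)
  expect_equal(m1$pooled_beta, full$beta, tolerance = 1e-12)
  expect_equal(m1$pooled_se, full$robust_se, tolerance = 1e-12)
  m10a <- split_and_fit(tab, ws, sp, n_groups = 10, seed = 8)
  m10b <- split_and_fit(tab, ws, sp, n_groups = 10, seed = 8)
  expect_equal(m10a$pooled_beta, m10b$pooled_beta, tolerance = 1e-15)
  # persons are never split across groups
  expect_equal(sum(vapply(m10a$fits, `[[`, numeric(1), "n_persons")),
               length(unique(tab$person_id)))
  # pooled estimate within 2 pooled SEs of the full-data fit
  expect_lt(abs(m10a$pooled_beta - full$beta), 2 * m10a$pooled_se)
})

test_that("single-pollutant fit matches the omitted-variable-bias closed form", {
  # independent pollutants: single and multi agree within 2 SEs
  set.seed(45)
  n <- 4e4
  tab <- data.frame(person_id = seq_len(n), year = 2000,
                    pm25 = rnorm(n, 8, 2), o3 = rnorm(n, 42, 4))
  p <- 0.03 + 7e-4 * (tab$pm25 - 8) + 8e-4 * (tab$o3 - 42)
  tab$death <- as.integer(runif(n) < p)
  ps <- covariate_spec(continuous = "o3", degree = 2)
  sp <- outcome_spec("pm25", copollutants = "o3")
  multi <- fit_weighted_lpm(tab, gps_weights(tab, "pm25", ps), sp)
  single <- single_pollutant_fit(tab, ps, sp)
  expect_lt(abs(single$beta - multi$beta),
            2 * sqrt(single$robust_se^2 + multi$robust_se^2))

  # correlated copollutant with its own effect: omitted-variable bias
  # bias = rd_o3 * cov(pm25, o3) / var(pm25)
  r <- 0.6
  o3c <- 42 + 4 * (r * (tab$pm25 - 8) / 2 + sqrt(1 - r^2) * rnorm(n))
  tab2 <- tab; tab2$o3 <- o3c
  p2 <- 0.03 + 7e-4 * (tab2$pm25 - 8) + 8e-4 * (tab2$o3 - 42)
  tab2$death <- as.integer(runif(n) < p2)
  single2 <- single_pollutant_fit(tab2, ps, sp)
  expected_bias <- 8e-4 * cov(tab2$pm25, tab2$o3) / var(tab2$pm25)
  expect_lt(abs(single2$beta - (7e-4 + expected_bias)), 3 * single2$robust_se)
  expect_gt(abs(single2$beta - 7e-4), 2 * single2$robust_se)  # visibly biased
})

test_that("rank-deficient outcome designs are reported", {
  tab <- small_cohort(n = 300, seed = 46)
  tab$dup <- tab$income
  sp <- outcome_spec("pm25", continuous = c("income", "dup"))
  expect_error(fit_weighted_lpm(tab, NULL, sp), "rank deficient")
})
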