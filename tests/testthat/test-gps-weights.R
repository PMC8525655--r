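# Stabilized GPS weights: Gaussian density models, the SW ratio, and
# winsorization, each checked against closed forms or hand/brute-force
# oracles plus large-sample properties.

test_that("marginal density model matches its closed form", {
  tab <- data.frame(pm25 = c(0, 1, 2))
  m <- fit_marginal_density(tab, "pm25")
  expect_equal(unname(m$coefficients), 1)
  expect_equal(m$residual_sd, 1)  # sqrt(RSS/(n-1)) = sd
  # density at the mean is the Gaussian peak 1/(sigma*sqrt(2*pi))
  expect_equal(dnorm(1, m$fitted[2], m$residual_sd), 1 / sqrt(2 * pi))
  expect_error(fit_marginal_density(data.frame(pm25 = rep(4, 5)), "pm25"),
               "zero variance")
  expect_error(fit_marginal_density(data.frame(pm25 = 1), "pm25"), "at least 2")
})

test_that("marginal fit recovers generating parameters at large n", {
  set.seed(31)
  tab <- data.frame(pm25 = rnorm(1e5, 8.18, 1.6))
  m <- fit_marginal_density(tab, "pm25")
  expect_lt(abs(unname(m$coefficients) - 8.18), 0.02)
  expect_lt(abs(m$residual_sd - 1.6), 0.02)
})

test_that("conditional density model nests the marginal and recovers a quadratic truth", {
  tab <- small_cohort(n = 300, seed = 32)
  m0 <- fit_marginal_density(tab, "pm25")
  mc <- fit_conditional_density(tab, "pm25", covariate_spec())
  expect_equal(unname(mc$coefficients[1]), unname(m0$coefficients[1]))
  expect_equal(mc$fitted, m0$fitted, tolerance = 1e-12)
  expect_equal(mc$residual_sd, m0$residual_sd)  # both use an n-1 denominator

  # generating-model recovery: x = 1 + 0.5 v + 0.2 v^2 + N(0,1)
  set.seed(33)
  n <- 1e4
  v <- rnorm(n)
  dat <- data.frame(x = 1 + 0.5 * v + 0.2 * v^2 + rnorm(n), v = v)
  fit <- fit_conditional_density(dat, "x", covariate_spec("v", degree = 2))
  # design standardizes v, so compare fitted means against the truth directly
  truth <- 1 + 0.5 * v + 0.2 * v^2
  expect_lt(max(abs(lm(fit$fitted ~ truth)$coef - c(0, 1))), 0.05)
  expect_lt(abs(fit$residual_sd - 1), 0.05)
})

test_that("degenerate and collinear conditional fits raise errors", {
  dat <- data.frame(x = c(0, 0, 2, 2), v = c(0, 0, 1, 1))
  expect_error(fit_conditional_density(dat, "x", covariate_spec(categorical = "v")),
               "degenerate")
  dat2 <- data.frame(x = rnorm(50), a = rnorm(50))
  dat2$b <- 2 * dat2$a
  expect_error(fit_conditional_density(dat2, "x", covariate_spec(c("a", "b"), degree = 1)),
               "rank deficient")
})

test_that("stabilized weights equal hand-computed Gaussian density ratios", {
  # identical models: every SW = 1
  tab <- small_cohort(n = 200, seed = 34)
  m0 <- fit_marginal_density(tab, "pm25")
  ws0 <- compute_stabilized_weights(tab, m0, m0)
  expect_equal(ws0$raw, rep(1, nrow(tab)))

  # two-row hand example: marginal N(1,1), conditional means (0.5, 1.5), sd 0.5
  tab2 <- data.frame(x = c(1, 1))
  marg <- structure(list(kind = "marginal", exposure = "x",
                         coefficients = c("(Intercept)" = 1), residual_sd = 1,
                         fitted = c(1, 1), n = 2L), class = "density_model")
  cond <- structure(list(kind = "conditional", exposure = "x",
                         coefficients = NULL, residual_sd = 0.5,
                         fitted = c(0.5, 1.5), n = 2L), class = "density_model")
  ws <- compute_stabilized_weights(tab2, marg, cond)
  phi <- function(x, m, s) exp(-(x - m)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  expect_equal(ws$raw, phi(1, 1, 1) / phi(1, c(0.5, 1.5), 0.5), tolerance = 1e-12)
})

test_that("raw weights average approximately 1 under a correct specification", {
  tab <- small_cohort(n = 14000, seed = 35)
  expect_gt(nrow(tab), 1e5)
  ws <- gps_weights(tab, "pm25", default_ps_spec(), truncate = NULL)
  expect_gt(mean(ws$raw), 0.95)
  expect_lt(mean(ws$raw), 1.05)
})

test_that("winsorization matches a brute-force sorted-list oracle and never reorders", {
  ws <- structure(list(numerator = rep(1, 100), denominator = rep(1, 100),
                       raw = as.numeric(1:100), truncated = as.numeric(1:100),
                       bounds = NULL, exposure = "x", n = 100L),
                  class = "weight_set")
  out <- truncate_weights(ws, 1, 99)
  q <- quantile(1:100, c(0.01, 0.99), type = 7, names = FALSE)
  # brute-force winsorization on the sorted list
  expect_equal(out$truncated, pmin(pmax(1:100, q[1]), q[2]))
  expect_equal(max(out$truncated), q[2])
  expect_equal(unname(out$bounds), q)
  # (0, 100) bounds are the identity
  id <- truncate_weights(ws, 0, 100)
  expect_equal(id$truncated, ws$raw)
  # all-equal weights unchanged
  wse <- ws; wse$raw <- rep(2, 100); wse$truncated <- wse$raw
  expect_equal(truncate_weights(wse)$truncated, rep(2, 100))
  # monotone transform: order preserved
  set.seed(36)
  wsr <- ws; wsr$raw <- rexp(100); wsr$truncated <- wsr$raw
  tr <- truncate_weights(wsr)$truncated
  expect_true(all(diff(tr[order(wsr$raw)]) >= 0))
  expect_error(truncate_weights(ws, 99, 1), "below")
})

test_that("weight scale invariance: scaling weights leaves point estimates unchanged", {
  tab <- small_cohort(n = 800, seed = 37)
  sp <- default_outcome_spec()
  ws <- gps_weights(tab, "pm25", default_ps_spec())
  f1 <- fit_weighted_lpm(tab, ws$truncated, sp)
  f2 <- fit_weighted_lpm(tab, 3.7 * ws$truncated, sp)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})
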