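# Synthetic open-cohort generator with known ground-truth additive effects.
# Persons are nested in synthetic postal areas; area-level covariates confound
# the exposures; annual death is drawn from a linear probability model so the
# configured risk differences are the true marginal causal effects.

.DIVISIONS <- c(
  "Pacific", "Southwest Central", "Northwest Central", "Northeast Central",
  "Southeast Central", "Mountain", "South Atlantic", "Middle Atlantic",
  "New England"
)

.AREA_COVARIATES <- c(
  "income", "poverty", "density", "education", "smoking", "bmi",
  "pct_hispanic", "dist_hospital"
)

#' Configuration for the synthetic open cohort
#'
#' Builds a validated configuration object for [generate_cohort()]. Defaults
#' describe a Medicare-like cohort of adults 65+ observed annually from 2000
#' to 2016 with staggered January entry, administrative censoring at end of
#' study, annual mortality near 3.9%, and three correlated pollutant exposures
#' whose marginal means/SDs match low-concentration US conditions
#' (PM2.5 mean 8.18 ug/m3, NO2 mean 19.80 ppb, warm-season O3 mean 41.94 ppb).
#'
#' Confounding is induced through a scalar confounder index built from
#' standardized area/individual covariates (`confounding_strength` gives the
#' per-covariate loadings, in exposure-SD units per covariate-SD; the special
#' name `income_sq` loads on the standardized square of income, so that a
#' linear-only propensity model is genuinely misspecified while a quadratic
#' one is correct). Exposure residuals are constructed so the marginal
#' exposure means, SDs and correlation matrix are exactly the configured ones
#' regardless of the confounding loadings.
#'
#' @param n_persons number of persons to simulate.
#' @param year_range integer pair, first and last calendar year of the study.
#' @param true_rd named vector of true additive risk differences per unit of
#'   exposure per year, on the probability scale.
#' @param baseline_annual_risk annual death probability at mean exposure and
#'   mean covariates.
#' @param exposure_means,exposure_sds named vectors over the three pollutants.
#' @param exposure_corr 3x3 correlation matrix (unit diagonal, symmetric,
#'   positive definite) of the pollutant exposures.
#' @param confounding_strength named loadings of covariates in the exposure
#'   model; set to an all-zero/empty vector for an unconfounded cohort.
#' @param covariate_effects named additive effects of standardized covariates
#'   on annual death probability.
#' @param n_areas number of synthetic postal areas persons are nested in.
#' @param seed integer RNG seed; the cohort is a deterministic function of the
#'   configuration including the seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_persons = 50000L,
                          year_range = c(2000L, 2016L),
                          true_rd = c(pm25 = 7.3e-4, no2 = 3e-5, o3 = 8.1e-4),
                          baseline_annual_risk = 0.039,
                          exposure_means = c(pm25 = 8.18, no2 = 19.80, o3 = 41.94),
                          exposure_sds = c(pm25 = 1.85, no2 = 9.50, o3 = 4.10),
                          exposure_corr = NULL,
                          confounding_strength = c(income = -0.20, poverty = 0.15,
                                                   smoking = 0.20, education = 0.15,
                                                   income_sq = 0.10),
                          covariate_effects = c(age = 0.010, male = 0.005,
                                                medicaid = 0.008, race_black = 0.002,
                                                income = -0.004, poverty = 0.003,
                                                density = 0.002, smoking = 0.004,
                                                bmi = 0.001, education = 0.002,
                                                income_sq = 0.002),
                          n_areas = 500L,
                          seed = 1L) {
  if (is.null(exposure_corr)) {
    exposure_corr <- matrix(c(1, 0.45, 0.30,
                              0.45, 1, 0.20,
                              0.30, 0.20, 1), 3, 3,
                            dimnames = list(names(exposure_means), names(exposure_means)))
  }
  cfg <- structure(list(
    n_persons = as.integer(n_persons),
    year_range = as.integer(year_range),
    true_rd = true_rd,
    baseline_annual_risk = baseline_annual_risk,
    exposure_means = exposure_means,
    exposure_sds = exposure_sds,
    exposure_corr = exposure_corr,
    confounding_strength = confounding_strength,
    covariate_effects = covariate_effects,
    n_areas = as.integer(n_areas),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_persons < 1L) stop("n_persons must be a positive integer")
  yr <- config$year_range
  if (length(yr) != 2L || yr[2] < yr[1]) stop("year_range must be an ordered pair of years")
  p <- config$baseline_annual_risk
  if (!is.finite(p) || p <= 0 || p >= 1) stop("baseline_annual_risk must lie in (0, 1)")
  if (any(!is.finite(config$true_rd))) stop("true_rd must be finite")
  C <- config$exposure_corr
  if (!isTRUE(all.equal(C, t(C))) || any(abs(diag(C) - 1) > 1e-12)) {
    stop("exposure_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("exposure_corr must be positive definite")
  if (any(config$exposure_sds <= 0)) stop("exposure_sds must be positive")
  if (!identical(sort(names(config$exposure_means)), sort(names(config$exposure_sds))) ||
      !identical(sort(names(config$exposure_means)), sort(names(config$true_rd)))) {
    stop("true_rd, exposure_means and exposure_sds must share names")
  }
  invisible(config)
}

# standardize with population-style sd; constant columns map to 0
.zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# resolve a confounder/effect key to a per-row standardized column
.covariate_column <- function(key, tab) {
  switch(key,
    income_sq = {
      z <- .zscore(tab$income)
      (z^2 - 1) / sqrt(2)
    },
    male = {
      m <- as.numeric(tab$sex == "Male"); m - mean(m)
    },
    medicaid = tab$medicaid - mean(tab$medicaid),
    race_black = {
      b <- as.numeric(tab$race == "Black"); b - mean(b)
    },
    {
      if (is.null(tab[[key]])) stop("unknown covariate in configuration: ", key)
      .zscore(tab[[key]])
    }
  )
}

#' Generate a synthetic open person-year cohort
#'
#' Simulates an open cohort with staggered entry (uniform over the study
#' years, entry in January), annual follow-up rows until death or the end of
#' the study, confounded multivariate-Gaussian pollutant exposures with a
#' small positive floor, and an annual death indicator drawn from an additive
#' (linear probability) mortality model. The returned table has one row per
#' person-year; `death` is 1 only on a person's final row.
#'
#' Death probabilities are clipped to `[1e-4, 1 - 1e-4]`; the clipped fraction
#' is recorded in `attr(x, "clip_fraction")` and a warning is raised when more
#' than 1% of rows would leave (0, 1) before clipping.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` (person-year table) with person id, calendar year,
#'   individual covariates (age, sex, race, medicaid), area-level covariates,
#'   census division, seasonal temperatures, the three exposures and `death`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_persons = 500, seed = 7))
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  y0 <- config$year_range[1]; y1 <- config$year_range[2]
  n <- config$n_persons
  A <- config$n_areas

  # synthetic postal areas: covariates drawn once per area
  area <- data.frame(
    income = 55000 + 12000 * stats::rnorm(A),
    poverty = pmax(1, 12 + 6 * stats::rnorm(A)),
    density = exp(6 + 1.4 * stats::rnorm(A)),
    education = pmax(1, 22 + 8 * stats::rnorm(A)),
    smoking = pmax(2, 18 + 5 * stats::rnorm(A)),
    bmi = 27.5 + 1.5 * stats::rnorm(A),
    pct_hispanic = pmax(0.2, 9 + 9 * stats::rnorm(A)),
    dist_hospital = pmax(0.2, exp(1.6 + 0.7 * stats::rnorm(A)))
  )
  warm_base <- 21 + 3.5 * stats::rnorm(A)
  cold_base <- 7 + 6 * stats::rnorm(A)
  division <- sample(.DIVISIONS, A, replace = TRUE)

  # persons
  p_area <- sample.int(A, n, replace = TRUE)
  entry_year <- y0 + sample.int(y1 - y0 + 1L, n, replace = TRUE) - 1L
  age_entry <- pmin(99, 65 + floor(stats::rexp(n, rate = 1 / 8)))
  sex <- ifelse(stats::runif(n) < 0.463, "Male", "Female")
  race <- sample(c("White", "Black", "Other"), n, replace = TRUE,
                 prob = c(0.848, 0.071, 0.081))
  z_inc_a <- .zscore(area$income)[p_area]
  z_pov_a <- .zscore(area$poverty)[p_area]
  medicaid <- as.integer(stats::runif(n) < stats::plogis(-2.35 + 0.5 * z_pov_a - 0.35 * z_inc_a))

  # expand to person-years (administrative censoring at y1)
  len <- y1 - entry_year + 1L
  pid <- rep(seq_len(n), len)
  year <- sequence(len) - 1L + rep(entry_year, len)
  N <- length(pid)
  aidx <- p_area[pid]

  tab <- data.frame(
    person_id = pid,
    year = year,
    age = age_entry[pid] + (year - entry_year[pid]),
    sex = factor(sex[pid], levels = c("Female", "Male")),
    race = factor(race[pid], levels = c("White", "Black", "Other")),
    medicaid = medicaid[pid],
    area_id = aidx,
    division = factor(division[aidx], levels = .DIVISIONS),
    warm_temp = warm_base[aidx] + 0.8 * stats::rnorm(N),
    cold_temp = cold_base[aidx] + 1.2 * stats::rnorm(N)
  )
  for (v in .AREA_COVARIATES) tab[[v]] <- area[[v]][aidx]

  # confounder index h in exposure-SD units
  cs <- config$confounding_strength
  cs <- cs[is.finite(cs) & cs != 0]
  if (length(cs)) {
    h <- rep(0, N)
    for (k in names(cs)) h <- h + cs[[k]] * .covariate_column(k, tab)
    vh <- mean((h - mean(h))^2)
  } else {
    h <- rep(0, N)
    vh <- 0
  }

  # residual covariance chosen so marginal means/SDs/correlations are exact
  nm <- names(config$exposure_means)
  C <- config$exposure_corr[nm, nm]
  s <- config$exposure_sds[nm]
  Cres <- C - vh
  diag(Cres) <- 1 - vh
  ok <- tryCatch({ R <- chol(diag(s) %*% Cres %*% diag(s)); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    stop("confounding_strength too large relative to exposure_corr: ",
         "residual exposure covariance is not positive definite")
  }
  E <- matrix(stats::rnorm(N * length(nm)), N, length(nm)) %*% R
  X <- E + outer(h, s)           # add s_j * h_i per column
  X <- sweep(X, 2, config$exposure_means[nm], "+")
  X <- pmax(X, 0.1)              # positivity floor
  colnames(X) <- nm
  for (j in nm) tab[[j]] <- X[, j]

  # additive mortality model, centered so mean risk ~ baseline
  p_raw <- rep(config$baseline_annual_risk, N)
  for (j in nm) p_raw <- p_raw + config$true_rd[[j]] * (tab[[j]] - config$exposure_means[[j]])
  ce <- config$covariate_effects
  ce <- ce[is.finite(ce) & ce != 0]
  for (k in names(ce)) p_raw <- p_raw + ce[[k]] * .covariate_column(k, tab)

  out_frac <- mean(p_raw <= 0 | p_raw >= 1)
  if (out_frac > 0.01) {
    warning(sprintf("%.2f%% of death probabilities fell outside (0,1) before clipping",
                    100 * out_frac))
  }
  p <- pmin(pmax(p_raw, 1e-4), 1 - 1e-4)
  clip_frac <- mean(p != p_raw)

  draw <- stats::runif(N) < p
  # keep rows up to and including each person's first death
  csum <- cumsum(draw)
  first <- cumsum(c(1L, len[-n]))
  base <- rep(csum[first] - draw[first], len)
  prior <- csum - draw - base
  keep <- prior == 0
  tab <- tab[keep, , drop = FALSE]
  tab$death <- as.integer(draw[keep])
  rownames(tab) <- NULL

  attr(tab, "clip_fraction") <- clip_frac
  attr(tab, "oob_fraction") <- out_frac
  attr(tab, "config") <- config
  tab
}

#' Ground-truth marginal risk difference for an exposure
#'
#' Because the simulated mortality model is linear in exposure, the configured
#' additive coefficient equals the marginal causal risk difference per unit of
#' exposure per year (up to probability clipping, which is kept below 1% of
#' rows under default settings).
#'
#' @param config a [cohort_config()] object.
#' @param exposure exposure name, e.g. `"pm25"`.
#' @return the true additive risk difference per unit-year.
#' @export
true_marginal_rd <- function(config, exposure) {
  validate_cohort_config(config)
  if (!exposure %in% names(config$true_rd)) {
    stop("unknown exposure: ", exposure)
  }
  unname(config$true_rd[[exposure]])
}

#' Default modelling covariates for the synthetic cohort
#'
#' Convenience accessors giving the continuous and categorical covariate
#' rosters used by the propensity-score and outcome models when analysing a
#' cohort produced by [generate_cohort()].
#'
#' @return character vector of column names.
#' @export
cohort_continuous_covariates <- function() {
  c(.AREA_COVARIATES, "warm_temp", "cold_temp", "age", "year")
}

#' @rdname cohort_continuous_covariates
#' @export
cohort_categorical_covariates <- function() {
  c("sex", "race", "medicaid", "division")
}

#' Validate structural invariants of a person-year table
#'
#' Checks that a table has at most one row per (person, year), consecutive
#' years and unit age increments within person, death only on a person's final
#' row, at most one death per person, and strictly positive exposures.
#'
#' @param table a person-year `data.frame`.
#' @param exposures exposure columns expected to be strictly positive.
#' @return invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_person_year_table <- function(table, exposures = c("pm25", "no2", "o3")) {
  stopifnot(is.data.frame(table))
  o <- order(table$person_id, table$year)
  tab <- table[o, ]
  if (anyDuplicated(tab[c("person_id", "year")])) {
    stop("duplicate (person_id, year) rows")
  }
  same <- tab$person_id[-1] == tab$person_id[-nrow(tab)]
  if (nrow(tab) > 1) {
    dy <- diff(tab$year)[same]
    if (any(dy != 1)) stop("years not consecutive within person")
    if (!is.null(tab$age)) {
      da <- diff(tab$age)[same]
      if (any(da != 1)) stop("age does not increment by 1 within person")
    }
  }
  deaths <- tapply(tab$death, tab$person_id, sum)
  if (any(deaths > 1)) stop("a person has more than one death")
  if (nrow(tab) > 1 && any(tab$death[-nrow(tab)][same] == 1)) {
    stop("death occurs before a person's final row")
  }
  for (e in intersect(exposures, names(tab))) {
    if (any(tab[[e]] <= 0)) stop("non-positive exposure values in ", e)
  }
  invisible(TRUE)
}
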