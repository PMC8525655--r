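# Shared fixtures built in code. Small cohorts are cached per test run so
# independent test files do not regenerate them.

small_cohort <- local({
  memo <- new.env()
  function(n = 2000, seed = 11, ...) {
    key <- paste(n, seed, length(list(...)), sep = "_")
    if (is.null(memo[[key]])) {
      memo[[key]] <- generate_cohort(cohort_config(n_persons = n, seed = seed, ...))
    }
    memo[[key]]
  }
})

# minimal hand-built person-year table
toy_table <- function() {
  data.frame(
    person_id = c(1, 1, 2, 2, 3),
    year = c(2000, 2001, 2000, 2001, 2000),
    age = c(70, 71, 80, 81, 65),
    pm25 = c(10, 11, 10, 12.5, 9),
    no2 = c(20, 21, 19, 22, 18),
    o3 = c(40, 41, 42, 43, 39),
    income = c(5, 5, 6, 6, 7),
    death = c(0, 1, 0, 0, 1)
  )
}

default_ps_spec <- function(degree = 2) {
  covariate_spec(
    continuous = c("no2", "o3", cohort_continuous_covariates()),
    categorical = cohort_categorical_covariates(),
    degree = degree
  )
}

default_outcome_spec <- function(exposure = "pm25", ...) {
  outcome_spec(exposure,
               copollutants = setdiff(c("pm25", "no2", "o3"), exposure),
               continuous = cohort_continuous_covariates(),
               categorical = cohort_categorical_covariates(), ...)
}

# pull (estimate, SE) out of either fit flavour
extract_bse <- function(f) {
  if (!is.null(f$pooled_beta)) c(f$pooled_beta, f$pooled_se) else c(f$beta, f$robust_se)
}
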