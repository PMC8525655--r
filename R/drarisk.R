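# One-call doubly-robust fit: stabilized GPS weights + weighted linear
# probability model (optionally split-and-pooled), balance diagnostics and a
# reporting-scale effect summary, returned as a single classed model object.

#' Doubly-robust additive risk fit for a continuous exposure
#'
#' Orchestrates the full estimator on an analysis-ready person-year table:
#' (1) stabilized inverse-probability weights from marginal and conditional
#' Gaussian exposure densities (quadratic covariate terms by default),
#' winsorized at the 1st/99th percentiles; (2) a weighted linear probability
#' model of annual death on the exposure, copollutants and covariates with a
#' heteroscedasticity-robust sandwich SE, fitted either on the full table or
#' in `n_groups` random person-level splits pooled by fixed-effects
#' meta-analysis; (3) weighted-correlation balance diagnostics; and (4) an
#' effect summary (risk-difference %, attributable cases, E-value).
#'
#' The estimate is doubly robust: consistent if either the propensity
#' (weight) model or the outcome model is correctly specified.
#'
#' @param data analysis-ready person-year `data.frame` (already restricted;
#'   see [restrict_cohort()]).
#' @param exposure exposure column name.
#' @param copollutants copollutant columns adjusted for in both models.
#' @param continuous,categorical adjustment covariates (defaults: the
#'   synthetic-cohort rosters).
#' @param ps_degree polynomial degree of the propensity model (2 = main,
#'   3 = sensitivity).
#' @param quadratic_or use quadratic instead of cubic polynomial terms in the
#'   outcome model (sensitivity).
#' @param cubic_terms passed to [outcome_spec()]; `NULL` for its default.
#' @param n_groups random split groups (1 = single full-data fit).
#' @param truncate weight winsorization percentiles.
#' @param cluster `"none"` (HC1) or `"person"`.
#' @param seed seed for the random split.
#' @param duration_years study duration; default = calendar-year span of
#'   `data`.
#' @param baseline_risk annual baseline risk for the E-value conversion;
#'   default = deaths / person-years of `data`.
#' @return an object of class `drarisk` with components `fit` (`meta_fit` or
#'   `lpm_fit`), `weights` (`weight_set`), `balance` (`balance_report`),
#'   `summary` (`effect_summary`) and the specs used.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_persons = 3000, seed = 2))
#' m <- drarisk(cohort, "pm25", copollutants = c("no2", "o3"), n_groups = 1)
#' print(m)
#' @export
drarisk <- function(data, exposure,
                    copollutants = character(),
                    continuous = intersect(cohort_continuous_covariates(), names(data)),
                    categorical = intersect(cohort_categorical_covariates(), names(data)),
                    ps_degree = 2L,
                    quadratic_or = FALSE,
                    cubic_terms = NULL,
                    n_groups = 10L,
                    truncate = c(1, 99),
                    cluster = c("none", "person"),
                    seed = NULL,
                    duration_years = NULL,
                    baseline_risk = NULL) {
  cluster <- match.arg(cluster)
  ps_spec <- covariate_spec(c(copollutants, continuous), categorical, ps_degree)
  o_spec <- outcome_spec(exposure, copollutants, continuous, categorical,
                         cubic_terms = cubic_terms,
                         quadratic_variant = quadratic_or)
  ws <- gps_weights(data, exposure, ps_spec, truncate)
  fit <- if (n_groups > 1L) {
    split_and_fit(data, ws, o_spec, n_groups, seed, cluster)
  } else {
    fit_weighted_lpm(data, ws, o_spec, cluster)
  }
  bal <- balance_report(data, ws, exposure, continuous)
  py <- nrow(data)
  dy <- duration_years %||% (max(data$year) - min(data$year) + 1L)
  br <- baseline_risk %||% (sum(data$death) / py)
  summ <- effect_summary(fit, py, dy, br)
  structure(list(call = match.call(), exposure = exposure,
                 fit = fit, weights = ws, balance = bal, summary = summ,
                 ps_spec = ps_spec, outcome_spec = o_spec,
                 n_persons = length(unique(data$person_id)),
                 person_years = py, duration_years = dy,
                 baseline_risk = br),
            class = "drarisk")
}

#' @export
print.drarisk <- function(x, ...) {
  cat("doubly-robust additive risk model\n")
  cat("  exposure:", x$exposure)
  if (length(x$outcome_spec$copollutants)) {
    cat("  (adjusted for ", paste(x$outcome_spec$copollutants, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  cat(sprintf("  n = %d persons, %d person-years over %d years\n",
              x$n_persons, x$person_years, x$duration_years))
  print(x$summary)
  invisible(x)
}

#' @export
coef.drarisk <- function(object, ...) {
  stats::setNames(extract_beta_se(object$fit)[1], object$exposure)
}

#' @export
vcov.drarisk <- function(object, ...) {
  v <- matrix(extract_beta_se(object$fit)[2]^2, 1, 1,
              dimnames = list(object$exposure, object$exposure))
  v
}

#' @export
confint.drarisk <- function(object, parm, level = 0.95, ...) {
  bse <- extract_beta_se(object$fit)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(bse[1] - z * bse[2], bse[1] + z * bse[2])
  dimnames(out) <- list(object$exposure,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  out
}

#' @export
summary.drarisk <- function(object, ...) {
  structure(list(obj = object), class = "summary.drarisk")
}

#' @export
print.summary.drarisk <- function(x, ...) {
  o <- x$obj
  print(o)
  cat("\nweights:\n")
  print(o$weights)
  cat("\nbalance:\n")
  print(o$balance)
  invisible(x)
}
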