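# Reporting-scale summaries: risk-difference percentages with 95% CIs,
# attributable cases per year, and E-values for unmeasured confounding.

#' Annual attributable cases for a unit exposure difference
#'
#' Evaluates `rd * person_years / duration_years`: the annual number of
#' deaths attributable to a one-unit difference in exposure across the
#' observed population. A non-positive risk difference returns `NA` (a
#' negative attributable count on a probability scale is not meaningful, so
#' it is not calculated).
#'
#' @param rd_per_unit_year risk difference per unit of exposure per year
#'   (probability scale).
#' @param person_years total person-years of observation.
#' @param duration_years duration of the study in calendar years.
#' @return attributable cases per year, or `NA_real_` when `rd <= 0`.
#' @examples
#' attributable_cases(7.3e-4, 267111005, 17)
#' @export
attributable_cases <- function(rd_per_unit_year, person_years, duration_years) {
  if (person_years <= 0 || duration_years <= 0) {
    stop("person_years and duration_years must be positive")
  }
  if (!is.finite(rd_per_unit_year) || rd_per_unit_year <= 0) return(NA_real_)
  rd_per_unit_year * person_years / duration_years
}

#' Convert an additive risk difference to a risk ratio
#'
#' `rr = (baseline_risk + rd) / baseline_risk`, the multiplicative-scale
#' bridge used to compute E-values from additive estimates.
#'
#' @param rd risk difference (probability scale).
#' @param baseline_risk baseline annual risk in (0, 1); `baseline_risk + rd`
#'   must also lie in (0, 1).
#' @return the implied risk ratio.
#' @export
rd_to_rr <- function(rd, baseline_risk) {
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    stop("baseline_risk must lie in (0, 1)")
  }
  if (baseline_risk + rd <= 0 || baseline_risk + rd >= 1) {
    stop("baseline_risk + rd must lie in (0, 1)")
  }
  (baseline_risk + rd) / baseline_risk
}

#' E-value for unmeasured confounding
#'
#' Minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need to have with both exposure and outcome to
#' fully explain away an observed risk ratio: for `rr >= 1`,
#' `E = rr + sqrt(rr * (rr - 1))`; a protective `rr < 1` is first inverted.
#'
#' @param rr observed risk ratio (> 0).
#' @return the E-value (>= 1).
#' @examples
#' e_value(2)   # 2 + sqrt(2)
#' @export
e_value <- function(rr) {
  if (!is.finite(rr) || rr <= 0) stop("rr must be positive")
  if (rr < 1) rr <- 1 / rr
  rr + sqrt(rr * (rr - 1))
}

#' Per-unit percent increase implied by a hazard ratio
#'
#' Converts a hazard ratio reported for an `increment`-unit exposure contrast
#' into the percent increase per single unit: `(hr^(1/increment) - 1) * 100`.
#' Used to compare multiplicative-scale literature estimates with additive
#' per-unit results.
#'
#' @param hr hazard ratio (> 0).
#' @param increment size of the exposure contrast the hazard ratio refers to.
#' @return percent increase per unit.
#' @examples
#' hr_per_unit(1.136, 10)  # ~1.28% per unit
#' @export
hr_per_unit <- function(hr, increment) {
  if (hr <= 0 || increment <= 0) stop("hr and increment must be positive")
  (hr^(1 / increment) - 1) * 100
}

#' Effect summary on the reporting scale
#'
#' Turns a fitted exposure coefficient into the quantities reported for this
#' kind of analysis: the risk difference as a percentage with its 95% CI,
#' annual attributable cases (point and CI endpoints each passed through
#' [attributable_cases()]), and the E-value of the point estimate after
#' conversion to a risk ratio against the cohort's annual baseline risk.
#'
#' @param fit an `lpm_fit` or `meta_fit` (or any list with `beta`-like fields
#'   `pooled_beta`/`pooled_se` or `beta`/`robust_se`).
#' @param person_years total person-years of the analysis dataset.
#' @param duration_years study duration in calendar years (17 for 2000-2016).
#' @param baseline_risk annual baseline death risk used for the risk-ratio
#'   conversion, typically deaths / person-years of the analysis dataset.
#' @return an object of class `effect_summary`.
#' @export
effect_summary <- function(fit, person_years, duration_years, baseline_risk) {
  bse <- extract_beta_se(fit)
  b <- bse[1]; se <- bse[2]
  z <- stats::qnorm(0.975)
  ci <- c(b - z * se, b + z * se)
  ev <- if (b == 0) 1 else e_value(rd_to_rr(b, baseline_risk))
  structure(list(
    rd_percent = 100 * b,
    ci95_percent = 100 * ci,
    beta = b, se = se,
    attributable_cases = attributable_cases(b, person_years, duration_years),
    attributable_ci = c(attributable_cases(ci[1], person_years, duration_years),
                        attributable_cases(ci[2], person_years, duration_years)),
    e_value = ev,
    baseline_risk_used = baseline_risk,
    person_years = person_years,
    duration_years = duration_years
  ), class = "effect_summary")
}

extract_beta_se <- function(fit) {
  if (is.numeric(fit) && length(fit) == 2L) return(fit)
  if (inherits(fit, "meta_fit") || (!is.null(fit$pooled_beta))) {
    c(fit$pooled_beta, fit$pooled_se)
  } else if (!is.null(fit$beta)) {
    c(fit$beta, fit$robust_se %||% fit$se)
  } else {
    stop("cannot extract an estimate and standard error from 'fit'")
  }
}

#' @export
print.effect_summary <- function(x, ...) {
  fmt_ac <- function(v) if (is.na(v)) "NA" else formatC(v, format = "f", digits = 1, big.mark = " ")
  cat("effect summary (per one-unit increase in exposure per year)\n")
  cat(sprintf("  risk difference: %.3f%% (95%% CI %.3f to %.3f)\n",
              x$rd_percent, x$ci95_percent[1], x$ci95_percent[2]))
  cat(sprintf("  attributable cases per year: %s (%s to %s)\n",
              fmt_ac(x$attributable_cases),
              fmt_ac(x$attributable_ci[1]), fmt_ac(x$attributable_ci[2])))
  cat(sprintf("  E-value (multiplicative scale): %.3f  [baseline risk %.4g]\n",
              x$e_value, x$baseline_risk_used))
  invisible(x)
}

#' @export
as.data.frame.effect_summary <- function(x, ...) {
  data.frame(rd_percent = x$rd_percent,
             ci_lo_percent = x$ci95_percent[1],
             ci_hi_percent = x$ci95_percent[2],
             attributable_cases = x$attributable_cases,
             attributable_lo = x$attributable_ci[1],
             attributable_hi = x$attributable_ci[2],
             e_value = x$e_value,
             baseline_risk = x$baseline_risk_used,
             person_years = x$person_years,
             duration_years = x$duration_years)
}
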