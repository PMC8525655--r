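# Weighted linear probability model for annual death: the exposure
# coefficient is the absolute risk difference per unit of exposure per year.
# Variance is a heteroscedasticity-consistent sandwich (HC1 by default,
# optionally clustered by person). Large tables can be fitted in random
# person-level splits pooled by fixed-effects meta-analysis.

#' Outcome model specification
#'
#' Describes the design of the weighted linear probability model: the exposure
#' of interest (entering linearly, its coefficient being the risk difference),
#' copollutants, continuous and categorical adjustment covariates, and the
#' subset of continuous terms that receive cubic polynomials (by default the
#' copollutants plus warm/cold temperature, age and median household income,
#' where present). `quadratic_variant = TRUE` downgrades those terms to
#' quadratic, the model-specification sensitivity analysis.
#'
#' @param exposure exposure column name.
#' @param copollutants other pollutant columns adjusted for.
#' @param continuous,categorical adjustment covariate names.
#' @param cubic_terms continuous terms (including copollutants) modelled with
#'   polynomials; must be a subset of `continuous` plus `copollutants`.
#' @param quadratic_variant use quadratic instead of cubic polynomials for
#'   `cubic_terms`.
#' @return an object of class `outcome_spec`.
#' @export
outcome_spec <- function(exposure,
                         copollutants = character(),
                         continuous = character(),
                         categorical = character(),
                         cubic_terms = NULL,
                         quadratic_variant = FALSE) {
  if (exposure %in% c(copollutants, continuous, categorical)) {
    stop("exposure must not appear among the covariates")
  }
  if (is.null(cubic_terms)) {
    cubic_terms <- c(copollutants,
                     intersect(c("warm_temp", "cold_temp", "age", "income"),
                               continuous))
  }
  extra <- setdiff(cubic_terms, c(continuous, copollutants))
  if (length(extra)) {
    stop("cubic_terms not among continuous covariates or copollutants: ",
         paste(extra, collapse = ", "))
  }
  structure(list(exposure = exposure, copollutants = copollutants,
                 continuous = continuous, categorical = categorical,
                 cubic_terms = cubic_terms,
                 quadratic_variant = isTRUE(quadratic_variant)),
            class = "outcome_spec")
}

# assemble the outcome design matrix: intercept + raw exposure + covariates
outcome_design <- function(table, spec) {
  poly_deg <- if (spec$quadratic_variant) 2L else 3L
  cont <- unique(c(spec$copollutants, spec$continuous))
  degrees <- stats::setNames(ifelse(cont %in% spec$cubic_terms, poly_deg, 1L), cont)
  Xc <- build_design(table, cont, spec$categorical, degrees, check_rank = FALSE)
  x <- table[[spec$exposure]]
  if (is.null(x)) stop("exposure column not found: ", spec$exposure)
  X <- cbind(Xc[, 1, drop = FALSE], x, Xc[, -1, drop = FALSE])
  colnames(X)[2] <- spec$exposure
  X
}

#' Fit the weighted linear probability model
#'
#' Weighted least squares of the binary death indicator on the exposure
#' (linear, untransformed — its coefficient is the absolute annual risk
#' difference per unit) plus the expanded covariate design. The reported
#' standard error is a heteroscedasticity-consistent sandwich: HC1 by default,
#' or clustered by person (`cluster = "person"`), which additionally allows
#' within-person dependence across a person's repeated annual rows.
#'
#' @param table person-year `data.frame`.
#' @param weights a `weight_set` (its winsorized weights are used) or a
#'   positive numeric vector aligned to rows; `NULL` for unweighted.
#' @param spec an [outcome_spec()].
#' @param cluster `"none"` (HC1) or `"person"` (person-clustered sandwich).
#' @return an object of class `lpm_fit` with elements `beta` (risk difference
#'   per unit-year), `robust_se`, full `coefficients`, robust `vcov`, the
#'   classical (model-based) SE for reference, and size metadata.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_persons = 2000, seed = 1))
#' sp <- outcome_spec("pm25", copollutants = c("no2", "o3"),
#'                    continuous = c("age", "income"), categorical = "sex")
#' fit <- fit_weighted_lpm(cohort, weights = NULL, spec = sp)
#' coef(fit)[1:3]
#' @export
fit_weighted_lpm <- function(table, weights, spec,
                             cluster = c("none", "person")) {
  cluster <- match.arg(cluster)
  stopifnot(inherits(spec, "outcome_spec"))
  w <- resolve_weights(weights, nrow(table))
  y <- table$death
  if (is.null(y)) stop("table has no 'death' column")
  X <- outcome_design(table, spec)
  fit <- stats::lm.wfit(X, y, w)
  if (any(is.na(fit$coefficients))) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "))
  }
  e <- as.numeric(fit$residuals)
  n <- nrow(X); k <- ncol(X)
  bread <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(bread) <- list(colnames(X), colnames(X))
  if (cluster == "none") {
    meat <- crossprod(X * (w * e))
    V <- bread %*% meat %*% bread * n / (n - k)
  } else {
    S <- rowsum((w * e) * X, group = table$person_id)
    G <- nrow(S)
    meat <- crossprod(S)
    V <- bread %*% meat %*% bread * (G / (G - 1)) * ((n - 1) / (n - k))
  }
  sigma2 <- sum(w * e^2) / (n - k)
  beta <- unname(fit$coefficients[spec$exposure])
  structure(list(beta = beta,
                 robust_se = sqrt(V[spec$exposure, spec$exposure]),
                 classical_se = sqrt(sigma2 * bread[spec$exposure, spec$exposure]),
                 coefficients = fit$coefficients,
                 vcov = V,
                 exposure = spec$exposure,
                 cluster = cluster,
                 n_rows = n,
                 n_persons = length(unique(table$person_id)),
                 person_years = n,
                 spec = spec),
            class = "lpm_fit")
}

resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "weight_set")) weights <- weights$truncated
  if (length(weights) != n) stop("weights are not aligned to the table rows")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be finite and strictly positive")
  }
  weights
}

#' Fixed-effects (inverse-variance) meta-analysis of fits
#'
#' Pools exposure coefficients across independent fits:
#' `pooled_beta = sum(b_i / v_i) / sum(1 / v_i)` with pooled variance
#' `1 / sum(1 / v_i)`, `v_i` the squared robust SE.
#'
#' @param results non-empty list; each element needs fields `beta` and
#'   `robust_se` (an [fit_weighted_lpm()] result, or a hand-built list).
#' @return an object of class `meta_fit`.
#' @export
meta_fixed <- function(results) {
  if (!length(results)) stop("empty result list")
  b <- vapply(results, function(r) as.numeric(r$beta), numeric(1))
  se <- vapply(results, function(r) as.numeric(r$robust_se), numeric(1))
  if (any(se <= 0)) stop("all standard errors must be positive")
  wi <- 1 / se^2
  pooled_beta <- sum(wi * b) / sum(wi)
  pooled_se <- sqrt(1 / sum(wi))
  nr <- vapply(results, function(r) as.numeric(r$n_rows %||% NA_real_), numeric(1))
  np <- vapply(results, function(r) as.numeric(r$n_persons %||% NA_real_), numeric(1))
  structure(list(pooled_beta = pooled_beta, pooled_se = pooled_se,
                 n_groups = length(results), fits = results,
                 exposure = results[[1]]$exposure %||% NA_character_,
                 n_rows = if (all(is.finite(nr))) sum(nr) else NA_real_,
                 n_persons = if (all(is.finite(np))) sum(np) else NA_real_,
                 person_years = if (all(is.finite(nr))) sum(nr) else NA_real_),
            class = "meta_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-sample fit pooled by fixed-effects meta-analysis
#'
#' Randomly partitions persons (never splitting a person across groups) into
#' `n_groups` groups, fits the weighted linear probability model in each, and
#' pools with [meta_fixed()]. `n_groups = 1` reduces exactly to a single
#' [fit_weighted_lpm()] call.
#'
#' @inheritParams fit_weighted_lpm
#' @param n_groups number of random groups.
#' @param seed optional RNG seed for the person partition.
#' @return a `meta_fit` with the per-group `lpm_fit`s in `$fits`.
#' @export
split_and_fit <- function(table, weights, spec, n_groups = 10L, seed = NULL,
                          cluster = c("none", "person")) {
  cluster <- match.arg(cluster)
  if (n_groups < 1L) stop("n_groups must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  persons <- unique(table$person_id)
  grp_of <- stats::setNames(sample(rep_len(seq_len(n_groups), length(persons))),
                            persons)
  g <- grp_of[as.character(table$person_id)]
  ws_full <- resolve_weights(weights, nrow(table))
  fits <- vector("list", n_groups)
  for (i in seq_len(n_groups)) {
    idx <- which(g == i)
    fits[[i]] <- tryCatch(
      fit_weighted_lpm(table[idx, , drop = FALSE], ws_full[idx], spec, cluster),
      error = function(e) {
        stop("group ", i, " fit failed (", conditionMessage(e),
             "); consider fewer groups", call. = FALSE)
      })
  }
  meta_fixed(fits)
}

#' Single-pollutant fit
#'
#' Re-runs the weighted analysis with the copollutants removed from both the
#' propensity (weight) design and the outcome design, for comparison with the
#' copollutant-adjusted main analysis.
#'
#' @param table person-year `data.frame`.
#' @param ps_spec [covariate_spec()] for the propensity model (copollutants,
#'   if present among its continuous terms, are removed).
#' @param spec [outcome_spec()] (its copollutants are removed).
#' @param truncate weight-winsorization percentiles.
#' @param cluster sandwich flavour, as in [fit_weighted_lpm()].
#' @return an `lpm_fit`.
#' @export
single_pollutant_fit <- function(table, ps_spec, spec, truncate = c(1, 99),
                                 cluster = c("none", "person")) {
  cluster <- match.arg(cluster)
  stopifnot(inherits(ps_spec, "covariate_spec"), inherits(spec, "outcome_spec"))
  ps1 <- covariate_spec(setdiff(ps_spec$continuous, spec$copollutants),
                        ps_spec$categorical, ps_spec$degree)
  sp1 <- outcome_spec(spec$exposure, copollutants = character(),
                      continuous = setdiff(spec$continuous, spec$copollutants),
                      categorical = spec$categorical,
                      cubic_terms = setdiff(spec$cubic_terms, spec$copollutants),
                      quadratic_variant = spec$quadratic_variant)
  ws <- gps_weights(table, spec$exposure, ps1, truncate)
  fit_weighted_lpm(table, ws, sp1, cluster)
}

#' @export
print.lpm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("weighted linear probability model fit: '%s'\n", x$exposure))
  cat(sprintf("  risk difference per unit-year: %.*g (robust SE %.*g, %s)\n",
              digits, x$beta, digits, x$robust_se,
              if (x$cluster == "person") "person-clustered" else "HC1"))
  cat(sprintf("  n = %d person-years, %d persons\n", x$n_rows, x$n_persons))
  invisible(x)
}

#' @export
coef.lpm_fit <- function(object, ...) object$coefficients

#' @export
vcov.lpm_fit <- function(object, ...) object$vcov

#' @export
confint.lpm_fit <- function(object, parm = object$exposure, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- sqrt(diag(object$vcov))[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
summary.lpm_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = object$coefficients / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  structure(list(fit = object, coefficients = tab), class = "summary.lpm_fit")
}

#' @export
print.summary.lpm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(utils::head(x$coefficients, 12), digits = 4)
  if (nrow(x$coefficients) > 12) {
    cat("  ... (", nrow(x$coefficients) - 12, " further covariate terms)\n", sep = "")
  }
  invisible(x)
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat(sprintf("fixed-effects meta-analysis of %d group fit(s): '%s'\n",
              x$n_groups, x$exposure))
  cat(sprintf("  pooled risk difference per unit-year: %.*g (SE %.*g)\n",
              digits, x$pooled_beta, digits, x$pooled_se))
  if (is.finite(x$n_rows)) {
    cat(sprintf("  n = %d person-years, %d persons\n", x$n_rows, x$n_persons))
  }
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) {
  stats::setNames(object$pooled_beta, object$exposure)
}

#' @export
confint.meta_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$pooled_beta - z * object$pooled_se,
               object$pooled_beta + z * object$pooled_se)
  dimnames(out) <- list(object$exposure,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  out
}
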