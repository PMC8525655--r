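# Generalized-propensity-score stabilized weights for a continuous exposure:
# SW_i = f(x_i) / f(x_i | v_i), with both densities Gaussian — the numerator
# from an intercept-only linear regression of exposure, the denominator from
# a linear regression of exposure on the covariates (quadratic terms for the
# continuous ones by default). Extreme weights are winsorized at the 1st and
# 99th percentiles.

#' Marginal Gaussian density model of an exposure
#'
#' Fits the intercept-only linear regression of the exposure; the implied
#' density is Gaussian with mean equal to the sample mean and standard
#' deviation equal to the residual standard deviation of the fit
#' (denominator n - 1).
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure column name.
#' @return an object of class `density_model` with `kind = "marginal"`.
#' @export
fit_marginal_density <- function(table, exposure) {
  x <- table[[exposure]]
  if (is.null(x)) stop("exposure column not found: ", exposure)
  if (length(x) < 2L) stop("need at least 2 observations")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate density: exposure has zero variance")
  }
  structure(list(kind = "marginal", exposure = exposure,
                 coefficients = c("(Intercept)" = mean(x)),
                 residual_sd = s, fitted = rep(mean(x), length(x)),
                 n = length(x)),
            class = "density_model")
}

#' Conditional Gaussian density model of an exposure given covariates
#'
#' Ordinary least squares of the exposure on the expanded covariate design
#' (polynomial terms of the stated degree for continuous covariates, one-hot
#' encoding with a reference level for categorical ones). The implied
#' conditional density is Gaussian with row-specific mean equal to the fitted
#' value and a common residual standard deviation.
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure column name.
#' @param spec a [covariate_spec()]; an empty spec reduces to the marginal
#'   model.
#' @return an object of class `density_model` with `kind = "conditional"`.
#' @export
fit_conditional_density <- function(table, exposure, spec) {
  stopifnot(inherits(spec, "covariate_spec"))
  x <- table[[exposure]]
  if (is.null(x)) stop("exposure column not found: ", exposure)
  degrees <- stats::setNames(rep(spec$degree, length(spec$continuous)), spec$continuous)
  X <- build_design(table, spec$continuous, spec$categorical, degrees)
  fit <- stats::lm.fit(X, x)
  if (any(is.na(fit$coefficients))) {
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)], collapse = ", "))
  }
  df <- length(x) - ncol(X)
  if (df < 1L) stop("not enough observations for the conditional model")
  sigma <- sqrt(sum(fit$residuals^2) / df)
  if (!is.finite(sigma) || sigma < 1e-10) {
    stop("degenerate conditional density: residual standard deviation is (near) zero")
  }
  structure(list(kind = "conditional", exposure = exposure,
                 coefficients = fit$coefficients,
                 residual_sd = sigma, fitted = as.numeric(fit$fitted.values),
                 n = length(x), spec = spec),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("%s Gaussian density model for '%s' (n = %d)\n",
              x$kind, x$exposure, x$n))
  cat(sprintf("  residual sd: %.5g\n", x$residual_sd))
  if (x$kind == "conditional") {
    cat(sprintf("  %d design columns\n", length(x$coefficients)))
  }
  invisible(x)
}

#' Stabilized inverse-probability weights for a continuous exposure
#'
#' Computes per-row `SW = f(x) / f(x | v)` from fitted marginal and
#' conditional density models evaluated at each row's observed exposure.
#' Under a correctly specified conditional model the raw weights average
#' approximately 1.
#'
#' @param table person-year `data.frame` the models were fitted on.
#' @param marginal,conditional [fit_marginal_density()] /
#'   [fit_conditional_density()] objects fitted on the same rows.
#' @return an object of class `weight_set` holding per-row numerator and
#'   denominator densities, raw weights, and (initially untruncated)
#'   analysis weights.
#' @export
compute_stabilized_weights <- function(table, marginal, conditional) {
  stopifnot(inherits(marginal, "density_model"),
            inherits(conditional, "density_model"))
  x <- table[[marginal$exposure]]
  if (length(x) != marginal$n || length(x) != conditional$n) {
    stop("models were not fitted on the same rows as the table")
  }
  num <- stats::dnorm(x, mean = marginal$fitted, sd = marginal$residual_sd)
  den <- stats::dnorm(x, mean = conditional$fitted, sd = conditional$residual_sd)
  if (any(den < 1e-300)) {
    bad <- which(den < 1e-300)
    stop("positivity violation: conditional density vanishes for rows ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  structure(list(numerator = num, denominator = den,
                 raw = num / den, truncated = num / den,
                 bounds = NULL, exposure = marginal$exposure,
                 n = length(x)),
            class = "weight_set")
}

#' Winsorize extreme stabilized weights
#'
#' Weights above the `upper_pct` percentile are set to the percentile value,
#' and weights below the `lower_pct` percentile to that value; interior
#' weights are unchanged (winsorization, not trimming — no rows are dropped).
#' Percentiles use the linear-interpolation convention (`quantile()` type 7).
#'
#' @param ws a `weight_set`.
#' @param lower_pct,upper_pct truncation percentiles (defaults 1 and 99).
#' @return the `weight_set` with `truncated` weights and `bounds` filled in.
#' @export
truncate_weights <- function(ws, lower_pct = 1, upper_pct = 99) {
  stopifnot(inherits(ws, "weight_set"))
  if (ws$n < 1L) stop("empty weight set")
  if (lower_pct >= upper_pct) stop("lower_pct must be below upper_pct")
  q <- stats::quantile(ws$raw, c(lower_pct, upper_pct) / 100, type = 7,
                       names = FALSE)
  ws$truncated <- pmin(pmax(ws$raw, q[1]), q[2])
  ws$bounds <- c(lower = q[1], upper = q[2])
  ws
}

#' One-call stabilized GPS weights
#'
#' Fits the marginal and conditional exposure density models, forms the
#' stabilized weight ratio, and winsorizes at the given percentiles.
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure column name.
#' @param spec [covariate_spec()] for the conditional (propensity) model.
#' @param truncate length-2 percentiles for [truncate_weights()], or `NULL`
#'   to skip truncation.
#' @return a `weight_set` with the fitted density models attached as
#'   attributes `marginal` and `conditional`.
#' @export
gps_weights <- function(table, exposure, spec, truncate = c(1, 99)) {
  marg <- fit_marginal_density(table, exposure)
  cond <- fit_conditional_density(table, exposure, spec)
  ws <- compute_stabilized_weights(table, marg, cond)
  if (!is.null(truncate)) ws <- truncate_weights(ws, truncate[1], truncate[2])
  attr(ws, "marginal") <- marg
  attr(ws, "conditional") <- cond
  ws
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("stabilized weight set for '%s' (n = %d)\n", x$exposure, x$n))
  cat(sprintf("  raw weights:    mean %.4f, range [%.4g, %.4g]\n",
              mean(x$raw), min(x$raw), max(x$raw)))
  if (!is.null(x$bounds)) {
    cat(sprintf("  winsorized at [%.4g, %.4g]; analysis weights mean %.4f\n",
                x$bounds[1], x$bounds[2], mean(x$truncated)))
  } else {
    cat("  not truncated\n")
  }
  invisible(x)
}

# subset a weight set by row index, preserving bounds
subset_weight_set <- function(ws, idx) {
  out <- ws
  out$numerator <- ws$numerator[idx]
  out$denominator <- ws$denominator[idx]
  out$raw <- ws$raw[idx]
  out$truncated <- ws$truncated[idx]
  out$n <- length(out$raw)
  attr(out, "marginal") <- NULL
  attr(out, "conditional") <- NULL
  out
}
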