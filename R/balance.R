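# Covariate balance diagnostics: (weighted) absolute Pearson correlations
# between the exposure and each continuous covariate, summarised by their
# average. Categorical covariates are excluded from this metric.

#' Weighted Pearson correlation
#'
#' Pearson correlation computed from weighted means, variances and
#' covariance. With equal weights this reduces to the ordinary correlation.
#'
#' @param x,c numeric vectors of equal length.
#' @param w strictly positive weights.
#' @return the weighted correlation coefficient.
#' @export
weighted_correlation <- function(x, c, w) {
  if (length(x) != length(c) || length(x) != length(w)) {
    stop("x, c and w must have equal lengths")
  }
  if (any(w <= 0)) stop("weights must be strictly positive")
  sw <- sum(w)
  mx <- sum(w * x) / sw
  mc <- sum(w * c) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vc <- sum(w * (c - mc)^2) / sw
  if (vx <= 0 || vc <= 0) stop("zero weighted variance")
  sum(w * (x - mx) * (c - mc)) / sw / sqrt(vx * vc)
}

#' Exposure-covariate balance report
#'
#' For each continuous covariate, the absolute correlation with the exposure
#' before weighting and under the analysis (winsorized) weights, plus the
#' averages of each column — the summary used to judge whether weighting
#' achieved balance. A second weight set (e.g. from a cubic instead of
#' quadratic propensity model) can be supplied for comparison.
#'
#' @param table person-year `data.frame`.
#' @param weights a `weight_set` or positive numeric vector.
#' @param exposure exposure column name.
#' @param continuous_covariates continuous covariate columns to include.
#' @param weights2 optional second weight set for a side-by-side comparison.
#' @param use_raw use raw instead of winsorized weights from a `weight_set`.
#' @return an object of class `balance_report`: a `data.frame` with one row
#'   per covariate and attributes `avg_unweighted`, `avg_weighted` (and
#'   `avg_weighted2` when applicable).
#' @export
balance_report <- function(table, weights, exposure, continuous_covariates,
                           weights2 = NULL, use_raw = FALSE) {
  pick <- function(w) {
    if (inherits(w, "weight_set")) {
      if (use_raw) w$raw else w$truncated
    } else w
  }
  w <- pick(weights)
  x <- table[[exposure]]
  if (is.null(x)) stop("exposure column not found: ", exposure)
  missing_cov <- setdiff(continuous_covariates, names(table))
  if (length(missing_cov)) {
    stop("covariate columns not found: ", paste(missing_cov, collapse = ", "))
  }
  one <- rep(1, nrow(table))
  r_un <- vapply(continuous_covariates,
                 function(v) abs(weighted_correlation(x, table[[v]], one)),
                 numeric(1))
  r_w <- vapply(continuous_covariates,
                function(v) abs(weighted_correlation(x, table[[v]], w)),
                numeric(1))
  out <- data.frame(covariate = continuous_covariates,
                    abs_cor_unweighted = unname(r_un),
                    abs_cor_weighted = unname(r_w),
                    row.names = NULL)
  if (!is.null(weights2)) {
    w2 <- pick(weights2)
    out$abs_cor_weighted2 <- vapply(continuous_covariates,
      function(v) abs(weighted_correlation(x, table[[v]], w2)), numeric(1))
    attr(out, "avg_weighted2") <- mean(out$abs_cor_weighted2)
  }
  attr(out, "avg_unweighted") <- mean(out$abs_cor_unweighted)
  attr(out, "avg_weighted") <- mean(out$abs_cor_weighted)
  attr(out, "exposure") <- exposure
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, digits = 4, ...) {
  cat(sprintf("covariate balance for '%s' (absolute correlation with exposure)\n",
              attr(x, "exposure")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("\naverage |r|: unweighted %.4f, weighted %.4f",
              attr(x, "avg_unweighted"), attr(x, "avg_weighted")))
  if (!is.null(attr(x, "avg_weighted2"))) {
    cat(sprintf(", alternative weights %.4f", attr(x, "avg_weighted2")))
  }
  cat("\n")
  invisible(x)
}
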