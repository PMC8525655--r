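# Effect-measure modification: run the full weighted analysis within strata
# (Medicaid, race, sex, age group, quartiles of area-level characteristics)
# and test pairwise differences between stratum coefficients.

#' Quartile strata over the person-year distribution
#'
#' Cuts a continuous column at its quartiles computed over person-years of
#' the analysis dataset (linear-interpolation quantiles), labelling strata
#' `"Q1"`-`"Q4"`.
#'
#' @param table person-year `data.frame`.
#' @param var continuous column name.
#' @return a factor of length `nrow(table)`.
#' @export
quartile_strata <- function(table, var) {
  x <- table[[var]]
  if (is.null(x)) stop("column not found: ", var)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cut(x, breaks = c(-Inf, q, Inf), labels = paste0("Q", 1:4), right = TRUE)
}

#' Age-group strata
#'
#' The conventional Medicare age bands: 65-74, 75-84, 85+.
#'
#' @param table person-year `data.frame` with an `age` column.
#' @return a factor of length `nrow(table)`.
#' @export
age_group_strata <- function(table) {
  cut(table$age, breaks = c(-Inf, 74, 84, Inf),
      labels = c("65-74", "75-84", "85+"), right = TRUE)
}

#' Stratified weighted analysis (effect-measure modification)
#'
#' Runs the weighted linear probability analysis separately within each level
#' of a stratification variable. By default the stabilized weights are refit
#' within each stratum (stratum-specific confounding structure); set
#' `refit_weights = FALSE` to reuse a global `weight_set` subset by stratum.
#'
#' @param table person-year `data.frame`.
#' @param stratum a column name, or a factor/vector of length `nrow(table)`.
#' @param ps_spec [covariate_spec()] for the propensity model.
#' @param spec [outcome_spec()] for the outcome model. If the stratification
#'   variable appears among its covariates it is dropped within strata.
#' @param refit_weights refit GPS weights within each stratum (default) or
#'   subset `weights`.
#' @param weights global `weight_set`, required when `refit_weights = FALSE`.
#' @param truncate winsorization percentiles for refitted weights.
#' @param n_groups random split groups per stratum (1 = single fit).
#' @param seed optional seed for split assignment.
#' @param cluster sandwich flavour.
#' @param duration_years,baseline_risk passed to [effect_summary()]; defaults
#'   are the stratum's calendar-year span and its deaths / person-years.
#' @param min_rows strata with fewer rows raise an error naming the stratum.
#' @return an object of class `emm_result`: a list with per-stratum entries
#'   (`fit`, `summary`, sizes) and a `table` data.frame shaped for a forest
#'   plot (level, rd%, CI bounds, person-years).
#' @export
stratified_fit <- function(table, stratum, ps_spec, spec,
                           refit_weights = TRUE, weights = NULL,
                           truncate = c(1, 99), n_groups = 1L, seed = NULL,
                           cluster = c("none", "person"),
                           duration_years = NULL, baseline_risk = NULL,
                           min_rows = 50L) {
  cluster <- match.arg(cluster)
  if (is.character(stratum) && length(stratum) == 1L) {
    stratum_var <- stratum
    svals <- table[[stratum]]
    if (is.null(svals)) stop("stratum column not found: ", stratum)
  } else {
    stratum_var <- deparse(substitute(stratum))[1]
    svals <- stratum
    if (length(svals) != nrow(table)) stop("stratum vector not aligned to table")
  }
  f <- if (is.factor(svals)) droplevels(svals) else factor(svals)
  if (!refit_weights && is.null(weights)) {
    stop("weights must be supplied when refit_weights = FALSE")
  }
  # the stratification variable cannot also be an adjustment covariate
  ps_s <- covariate_spec(setdiff(ps_spec$continuous, stratum_var),
                         setdiff(ps_spec$categorical, stratum_var),
                         ps_spec$degree)
  sp_s <- outcome_spec(spec$exposure, spec$copollutants,
                       setdiff(spec$continuous, stratum_var),
                       setdiff(spec$categorical, stratum_var),
                       cubic_terms = setdiff(spec$cubic_terms, stratum_var),
                       quadratic_variant = spec$quadratic_variant)
  results <- list()
  for (lev in levels(f)) {
    idx <- which(f == lev)
    if (length(idx) < min_rows) {
      stop("stratum too small for a full-rank fit: ", stratum_var, " = ", lev)
    }
    sub <- table[idx, , drop = FALSE]
    ws <- if (refit_weights) {
      gps_weights(sub, sp_s$exposure, ps_s, truncate)
    } else {
      subset_weight_set(weights, idx)
    }
    fit <- if (n_groups > 1L) {
      split_and_fit(sub, ws, sp_s, n_groups, seed, cluster)
    } else {
      fit_weighted_lpm(sub, ws, sp_s, cluster)
    }
    py <- nrow(sub)
    dy <- duration_years %||% (max(sub$year) - min(sub$year) + 1L)
    br <- baseline_risk %||% (sum(sub$death) / py)
    results[[lev]] <- list(level = lev, fit = fit,
                           summary = effect_summary(fit, py, dy, br),
                           n_persons = length(unique(sub$person_id)),
                           person_years = py)
  }
  bs <- t(vapply(results, function(r) extract_beta_se(r$fit), numeric(2)))
  z <- stats::qnorm(0.975)
  tab <- data.frame(stratum = stratum_var,
                    level = names(results),
                    rd_percent = 100 * bs[, 1],
                    lo_percent = 100 * (bs[, 1] - z * bs[, 2]),
                    hi_percent = 100 * (bs[, 1] + z * bs[, 2]),
                    n_persons = vapply(results, `[[`, numeric(1), "n_persons"),
                    person_years = vapply(results, `[[`, numeric(1), "person_years"),
                    row.names = NULL)
  structure(list(stratum = stratum_var, results = results, table = tab),
            class = "emm_result")
}

#' Pairwise comparison of stratum coefficients
#'
#' Two-sided z-test for the difference between two independent stratum
#' estimates: `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param a,b fits (`lpm_fit`/`meta_fit`), length-2 numeric `(beta, se)`
#'   vectors, or lists with `beta`/`robust_se` fields.
#' @param labels optional length-2 labels of the compared levels.
#' @param alpha significance level for the `significant` flag.
#' @return an object of class `pairwise_comparison` with fields `z`, `p`,
#'   `significant`, `levels`.
#' @export
pairwise_compare <- function(a, b, labels = c("a", "b"), alpha = 0.05) {
  ba <- extract_beta_se(a); bb <- extract_beta_se(b)
  v <- ba[2]^2 + bb[2]^2
  if (v <= 0) stop("zero combined variance")
  z <- (ba[1] - bb[1]) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(levels = labels, z = unname(z), p = unname(p),
                 significant = p < alpha),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("pairwise comparison %s vs %s: z = %.3f, p = %.4g%s\n",
              x$levels[1], x$levels[2], x$z, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' All pairwise stratum comparisons
#'
#' @param emm an `emm_result` from [stratified_fit()].
#' @param alpha significance level.
#' @return a `data.frame` with one row per unordered level pair.
#' @export
pairwise_compare_all <- function(emm, alpha = 0.05) {
  stopifnot(inherits(emm, "emm_result"))
  levs <- names(emm$results)
  out <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (i < j) {
      pc <- pairwise_compare(emm$results[[i]]$fit, emm$results[[j]]$fit,
                             labels = c(levs[i], levs[j]), alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(level_a = levs[i], level_b = levs[j],
                                            z = pc$z, p = pc$p,
                                            significant = pc$significant)
    }
  }
  do.call(rbind, out)
}

#' @export
print.emm_result <- function(x, ...) {
  cat(sprintf("stratified analysis by '%s' (%d strata)\n", x$stratum,
              length(x$results)))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Minimal forest plot of stratified estimates
#'
#' @param x an `emm_result`.
#' @param xlab x-axis label.
#' @param ... further arguments passed to `plot()`.
#' @export
plot.emm_result <- function(x, xlab = "risk difference per unit-year (%)", ...) {
  tab <- x$table
  k <- nrow(tab)
  ypos <- rev(seq_len(k))
  plot(tab$rd_percent, ypos, xlim = range(c(tab$lo_percent, tab$hi_percent, 0)),
       ylim = c(0.5, k + 0.5), pch = 19, yaxt = "n", ylab = "", xlab = xlab,
       main = paste("stratified by", x$stratum), ...)
  graphics::segments(tab$lo_percent, ypos, tab$hi_percent, ypos)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = ypos, labels = tab$level, las = 1)
  invisible(x)
}
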