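# Cohort restriction rules for low-concentration analyses: person-level
# always-below-cap exposure histories, removal of the lowest exposure
# percentiles, and complete-case filtering. The pipeline applies them in the
# fixed order cap -> percentile -> missing.

#' Restriction rules for a low-concentration cohort
#'
#' @param caps named vector of maximum allowed concentrations per exposure.
#'   Defaults follow US regulatory limits for annual PM2.5 (12 ug/m3) and NO2
#'   (53 ppb), and a pragmatic 50 ppb for warm-season O3, which has no
#'   long-term standard.
#' @param low_percentile percentile (0-50) of the post-cap exposure
#'   distribution below which person-years are dropped; default 3.
#' @param percentile_level `"record"` (drop person-years; default) or
#'   `"person"` (drop whole persons whose minimum exposure falls below the
#'   threshold), provided for sensitivity analyses.
#' @return an object of class `restriction_spec`.
#' @export
restriction_spec <- function(caps = c(pm25 = 12, no2 = 53, o3 = 50),
                             low_percentile = 3,
                             percentile_level = c("record", "person")) {
  percentile_level <- match.arg(percentile_level)
  if (any(caps <= 0)) stop("caps must be positive")
  if (low_percentile < 0 || low_percentile >= 50) {
    stop("low_percentile must lie in [0, 50)")
  }
  structure(list(caps = caps, low_percentile = low_percentile,
                 percentile_level = percentile_level),
            class = "restriction_spec")
}

#' Restrict to persons always exposed below a concentration cap
#'
#' Removes all rows of any person with at least one follow-up year in which
#' the exposure exceeds `cap` (person-level exclusion: a single high year
#' excludes the person's entire history). Comparison is `exposure > cap`, so
#' years exactly at the cap are kept.
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure column name.
#' @param cap maximum allowed concentration.
#' @return the restricted person-year table.
#' @export
apply_concentration_cap <- function(table, exposure, cap) {
  if (is.null(table[[exposure]])) stop("exposure column not found: ", exposure)
  over <- unique(table$person_id[table[[exposure]] > cap])
  out <- table[!(table$person_id %in% over), , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no persons satisfy restriction: every person exceeds the cap for ",
         exposure)
  }
  out
}

#' Drop the lowest percentiles of an exposure
#'
#' Removes person-years whose exposure is strictly below the `pct`-th
#' percentile of the (post-cap) person-year exposure distribution. The
#' percentile uses the linear-interpolation convention (`quantile()` type 7);
#' ties at the threshold are kept. Intended to be applied after
#' [apply_concentration_cap()]. With `level = "person"`, persons whose minimum
#' exposure falls below the threshold are removed entirely.
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure column name.
#' @param pct percentile in `[0, 50)`.
#' @param level `"record"` or `"person"`.
#' @return the restricted table.
#' @export
drop_low_percentile <- function(table, exposure, pct = 3,
                                level = c("record", "person")) {
  level <- match.arg(level)
  if (is.null(table[[exposure]])) stop("exposure column not found: ", exposure)
  if (pct < 0 || pct >= 50) stop("pct must lie in [0, 50)")
  if (pct == 0) return(table)
  thr <- stats::quantile(table[[exposure]], pct / 100, type = 7, names = FALSE)
  if (level == "record") {
    table[table[[exposure]] >= thr, , drop = FALSE]
  } else {
    pmin_ <- tapply(table[[exposure]], table$person_id, min)
    low <- names(pmin_)[pmin_ < thr]
    table[!(as.character(table$person_id) %in% low), , drop = FALSE]
  }
}

#' Complete-case filter over model columns
#'
#' Drops rows with any missing value among the given columns (all columns by
#' default), reporting the removed fraction. A warning is raised when more
#' than 10% of rows are removed, since the method assumes missingness is rare
#' and at random.
#'
#' @param table person-year `data.frame`.
#' @param columns columns to require complete; default all.
#' @param verbose emit a message with the removed fraction.
#' @return the complete-case table.
#' @export
drop_missing <- function(table, columns = names(table), verbose = FALSE) {
  cc <- stats::complete.cases(table[, columns, drop = FALSE])
  frac <- mean(!cc)
  if (frac > 0.10) {
    warning(sprintf("%.1f%% of rows removed as incomplete; missing-at-random assumption is doubtful", 100 * frac))
  } else if (verbose && frac > 0) {
    message(sprintf("complete-case filter removed %.2f%% of rows", 100 * frac))
  }
  table[cc, , drop = FALSE]
}

#' Apply all restriction rules in canonical order
#'
#' Cap (person-level), then low-percentile drop, then complete-case filter —
#' the fixed order the pipeline guarantees.
#'
#' @param table person-year `data.frame`.
#' @param exposure exposure under analysis.
#' @param spec a [restriction_spec()].
#' @return the restricted table, with row/person counts per stage in
#'   `attr(x, "restriction_counts")`.
#' @export
restrict_cohort <- function(table, exposure, spec = restriction_spec()) {
  stopifnot(inherits(spec, "restriction_spec"))
  counts <- list(input = c(rows = nrow(table), persons = length(unique(table$person_id))))
  cap <- spec$caps[[exposure]]
  if (!is.null(cap) && is.finite(cap)) {
    table <- apply_concentration_cap(table, exposure, cap)
  }
  counts$after_cap <- c(rows = nrow(table), persons = length(unique(table$person_id)))
  table <- drop_low_percentile(table, exposure, spec$low_percentile,
                               level = spec$percentile_level)
  counts$after_percentile <- c(rows = nrow(table), persons = length(unique(table$person_id)))
  table <- drop_missing(table)
  counts$after_missing <- c(rows = nrow(table), persons = length(unique(table$person_id)))
  attr(table, "restriction_counts") <- counts
  table
}
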