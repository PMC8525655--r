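# File-based end-to-end pipeline: simulate (or read) -> restrict -> weights
# -> fit -> summarize -> balance -> EMM, with a machine-readable manifest.
# Stage outputs are plain-text files (CSV for tables, JSON for results) so
# any stage can be inspected or rerun in isolation; all randomness flows from
# a single root seed expanded per stage.

#' Configuration of a pipeline run
#'
#' @param exposure exposure under analysis (`"pm25"`, `"no2"` or `"o3"`).
#' @param copollutants copollutants adjusted for in both models; default the
#'   other two pollutants.
#' @param cohort a [cohort_config()] used when no `input_csv` is given.
#' @param input_csv optional path to a person-year CSV to analyse instead of
#'   simulating.
#' @param restriction a [restriction_spec()].
#' @param sensitivity `"main"` (quadratic propensity model, cubic outcome
#'   terms), `"cubic_ps"` (cubic propensity model) or `"quadratic_or"`
#'   (quadratic outcome terms).
#' @param single_pollutant also run the single-pollutant comparison fit.
#' @param n_groups random split groups for the outcome fit.
#' @param emm_vars stratification variables for the effect-measure
#'   modification stage (`NULL` to skip). Quartile variables are recognised
#'   by the suffix `"_q"` (e.g. `"income_q"`), `"age_group"` by name.
#' @param truncate weight winsorization percentiles.
#' @param cluster sandwich flavour.
#' @param seed root seed; per-stage seeds are derived from it.
#' @param write_table also write the restricted analysis table to CSV (off by
#'   default; it can be large).
#' @return an object of class `run_config`.
#' @export
run_config <- function(exposure = "pm25",
                       copollutants = NULL,
                       cohort = cohort_config(),
                       input_csv = NULL,
                       restriction = restriction_spec(),
                       sensitivity = c("main", "cubic_ps", "quadratic_or"),
                       single_pollutant = FALSE,
                       n_groups = 10L,
                       emm_vars = NULL,
                       truncate = c(1, 99),
                       cluster = c("none", "person"),
                       seed = 1L,
                       write_table = FALSE) {
  sensitivity <- match.arg(sensitivity)
  cluster <- match.arg(cluster)
  if (!exposure %in% c("pm25", "no2", "o3")) {
    stop("exposure must be one of pm25, no2, o3")
  }
  if (is.null(copollutants)) {
    copollutants <- setdiff(c("pm25", "no2", "o3"), exposure)
  }
  structure(list(exposure = exposure, copollutants = copollutants,
                 cohort = cohort, input_csv = input_csv,
                 restriction = restriction, sensitivity = sensitivity,
                 single_pollutant = isTRUE(single_pollutant),
                 n_groups = as.integer(n_groups), emm_vars = emm_vars,
                 truncate = truncate, cluster = cluster,
                 seed = as.integer(seed), write_table = isTRUE(write_table)),
            class = "run_config")
}

emm_stratum_values <- function(table, var) {
  if (var == "age_group") return(age_group_strata(table))
  if (grepl("_q$", var)) {
    base <- sub("_q$", "", var)
    if (is.null(table[[base]])) stop("unknown quartile stratum variable: ", var)
    return(quartile_strata(table, base))
  }
  if (is.null(table[[var]])) stop("unknown stratum variable: ", var)
  table[[var]]
}

#' Run the full pipeline and write artifacts
#'
#' Executes simulate/load, restriction (cap, low-percentile drop,
#' complete-case), stabilized weights, the split-and-pooled weighted linear
#' probability fit, the effect summary, balance diagnostics and (optionally)
#' stratified effect-measure modification, writing each stage's output plus a
#' `manifest.json` (config echo, derived stage seeds, row/person counts per
#' stage, runtimes) to `out_dir`. Runs are deterministic given the config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory results (`model` — a
#'   [drarisk] object —, `single_pollutant`, `emm`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  set.seed(config$seed)
  stage_seeds <- sample.int(2147483646L, 4L)
  manifest <- list(config = config_echo(config), stage_seeds = stage_seeds,
                   stages = list())
  fail <- function(stage, e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  timed <- function(stage, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    manifest$stages[[stage]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), ts, units = "secs")))
    res
  }
  counts <- function(tab) list(rows = nrow(tab),
                               persons = length(unique(tab$person_id)))

  # 1. simulate or load
  table <- timed("simulate", {
    if (!is.null(config$input_csv)) {
      utils::read.csv(config$input_csv)
    } else {
      cfg <- config$cohort
      cfg$seed <- stage_seeds[1]
      generate_cohort(cfg)
    }
  })
  manifest$stages$simulate$counts <- counts(table)

  # 2. restriction (fixed order: cap -> percentile -> missing)
  table <- timed("restrict", restrict_cohort(table, config$exposure, config$restriction))
  manifest$stages$restrict$counts <- counts(table)
  manifest$stages$restrict$detail <- attr(table, "restriction_counts")
  if (config$write_table) {
    utils::write.csv(table, file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE)
  }

  # 3..5 weights, fit, summaries via the model object
  ps_degree <- if (config$sensitivity == "cubic_ps") 3L else 2L
  quadratic_or <- config$sensitivity == "quadratic_or"
  model <- timed("fit", drarisk(
    table, config$exposure, copollutants = config$copollutants,
    ps_degree = ps_degree, quadratic_or = quadratic_or,
    n_groups = config$n_groups, truncate = config$truncate,
    cluster = config$cluster, seed = stage_seeds[2]))
  manifest$stages$fit$counts <- counts(table)

  utils::write.csv(
    data.frame(person_id = table$person_id, year = table$year,
               raw_weight = model$weights$raw,
               truncated_weight = model$weights$truncated),
    file.path(out_dir, "weights.csv"), row.names = FALSE)
  bse <- extract_beta_se(model$fit)
  jsonlite::write_json(list(
    exposure = config$exposure, sensitivity = config$sensitivity,
    beta = bse[1], se = bse[2],
    ci95 = unname(c(confint(model))),
    n_groups = config$n_groups,
    n_persons = model$n_persons, person_years = model$person_years),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cbind(stratum = "all", level = "all",
                         as.data.frame(model$summary)),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$balance),
                   file.path(out_dir, "balance.csv"), row.names = FALSE)

  sp_fit <- NULL
  if (config$single_pollutant) {
    sp_fit <- timed("single_pollutant",
                    single_pollutant_fit(table, model$ps_spec,
                                         model$outcome_spec, config$truncate,
                                         config$cluster))
    jsonlite::write_json(list(beta = sp_fit$beta, se = sp_fit$robust_se),
                         file.path(out_dir, "single_pollutant.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # 6. effect-measure modification
  emm <- NULL
  if (length(config$emm_vars)) {
    emm <- timed("emm", {
      set.seed(stage_seeds[3])
      out <- list()
      for (v in config$emm_vars) {
        strat <- emm_stratum_values(table, v)
        res <- stratified_fit(table, strat, model$ps_spec, model$outcome_spec,
                              cluster = config$cluster)
        res$stratum <- v
        res$table$stratum <- v
        out[[v]] <- res
      }
      out
    })
    emm_tab <- do.call(rbind, lapply(emm, `[[`, "table"))
    utils::write.csv(emm_tab, file.path(out_dir, "emm.csv"), row.names = FALSE)
  }

  manifest$runtime_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(list(model = model, single_pollutant = sp_fit, emm = emm,
                 manifest = manifest))
}

# JSON-serialisable echo of the configuration (named vectors become objects
# so names survive the round trip)
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  for (f in c("true_rd", "exposure_means", "exposure_sds",
              "confounding_strength", "covariate_effects")) {
    cfg$cohort[[f]] <- as.list(cfg$cohort[[f]])
  }
  cfg$cohort$exposure_corr <- as.vector(cfg$cohort$exposure_corr)
  cfg$restriction <- unclass(cfg$restriction)
  cfg$restriction$caps <- as.list(cfg$restriction$caps)
  cfg
}

#' Write / read a run configuration as JSON
#'
#' Plain-text round-trip of a [run_config()] (and its nested cohort and
#' restriction specifications) for reproducible, file-driven runs.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config_echo(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coh <- j$cohort
  cc <- cohort_config(
    n_persons = coh$n_persons, year_range = coh$year_range,
    true_rd = unlist(coh$true_rd), baseline_annual_risk = coh$baseline_annual_risk,
    exposure_means = unlist(coh$exposure_means),
    exposure_sds = unlist(coh$exposure_sds),
    exposure_corr = matrix(coh$exposure_corr, 3, 3,
                           dimnames = list(names(unlist(coh$exposure_means)),
                                           names(unlist(coh$exposure_means)))),
    confounding_strength = unlist(coh$confounding_strength),
    covariate_effects = unlist(coh$covariate_effects),
    n_areas = coh$n_areas, seed = coh$seed)
  rs <- restriction_spec(unlist(j$restriction$caps),
                         j$restriction$low_percentile,
                         j$restriction$percentile_level)
  run_config(exposure = j$exposure, copollutants = unlist(j$copollutants),
             cohort = cc, input_csv = j$input_csv, restriction = rs,
             sensitivity = j$sensitivity,
             single_pollutant = isTRUE(j$single_pollutant),
             n_groups = j$n_groups, emm_vars = unlist(j$emm_vars),
             truncate = unlist(j$truncate), cluster = j$cluster,
             seed = j$seed, write_table = isTRUE(j$write_table))
}

#' Write a person-year table to CSV
#'
#' Canonical plain-text serialisation of the person-year schema (one row per
#' person-year; see [generate_cohort()] for the columns).
#'
#' @param table person-year `data.frame`.
#' @param path file path.
#' @export
write_person_year_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_person_year_csv
#' @param stringsAsFactors convert character columns (sex, race, division) to
#'   factors on read.
#' @export
read_person_year_csv <- function(path, stringsAsFactors = TRUE) {
  tab <- utils::read.csv(path)
  if (stringsAsFactors) {
    for (v in intersect(c("sex", "race", "division"), names(tab))) {
      tab[[v]] <- factor(tab[[v]])
    }
  }
  tab
}
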