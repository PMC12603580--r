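# Orchestration: a flat, human-editable run configuration, a seeded
# end-to-end pipeline (simulate -> preprocess -> term analysis -> loss
# analysis) with a machine-readable manifest, and report assembly.

#' Pipeline run configuration
#'
#' All thresholds default to the package's documented decisions; all
#' randomness flows from the single root `seed` via named substreams
#' (cohort generation, control matching), so stages are independently
#' reproducible. The configuration round-trips through a YAML file unchanged
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param out_dir output directory for all result files.
#' @param seed root seed.
#' @param daily_path,profiles_path input CSVs; `NULL` means a synthetic
#'   cohort of `simulate_n` pregnancies is generated into `out_dir`.
#' @param simulate_n cohort size when simulating.
#' @param metrics metrics to analyze.
#' @param df_time,df_cov,df_loss spline degrees of freedom (gestational-age
#'   trend, covariate splines, pre-loss day spline).
#' @param availability_threshold minimum data availability per window.
#' @param baseline_min_days,baseline_sd_floor baseline validity rules.
#' @param interpolation_max_gap daily-interpolation gap cap (days).
#' @param onset_threshold_z divergence-onset threshold (z units).
#' @param loss_min_coverage control coverage requirement in matched windows.
#' @param covariates also fit the age/BMI moderation models.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir, seed = 1L,
                       daily_path = NULL, profiles_path = NULL,
                       simulate_n = 200L,
                       metrics = c("temp_peak", "hr", "hrv", "rr", "steps",
                                   "time_in_bed", "time_asleep", "time_awake"),
                       df_time = 8L, df_cov = 3L, df_loss = 3L,
                       availability_threshold = 0.40,
                       baseline_min_days = 7L, baseline_sd_floor = 1e-6,
                       interpolation_max_gap = 7L,
                       onset_threshold_z = 0.25,
                       loss_min_coverage = 0.40,
                       covariates = FALSE) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir))
    stop("config field 'out_dir' is required")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              daily_path = daily_path, profiles_path = profiles_path,
              simulate_n = as.integer(simulate_n), metrics = metrics,
              df_time = as.integer(df_time), df_cov = as.integer(df_cov),
              df_loss = as.integer(df_loss),
              availability_threshold = availability_threshold,
              baseline_min_days = as.integer(baseline_min_days),
              baseline_sd_floor = baseline_sd_floor,
              interpolation_max_gap = as.integer(interpolation_max_gap),
              onset_threshold_z = onset_threshold_z,
              loss_min_coverage = loss_min_coverage,
              covariates = isTRUE(covariates))
  if (!is.null(cfg$daily_path) && is.null(cfg$profiles_path))
    stop("config field 'profiles_path' is required when 'daily_path' is set")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), preprocessing to
#' weekly z-scores, the term-trajectory model per metric, the pre-loss
#' divergence model per metric, and writes versioned outputs plus a
#' machine-readable run manifest (input hashes, seed, package version) into
#' `config$out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the per-metric `trend` and `loss` results
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- substream_seeds(config$seed, 2L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (is.null(config$daily_path)) {
      cc <- cohort_config(n_pregnancies = config$simulate_n, seed = seeds[1L])
      ch <- generate_cohort(cc)
      write_cohort(ch$profiles, ch$daily, config$out_dir)
      ch
    } else {
      list(profiles = as.data.frame(data.table::fread(config$profiles_path,
                                                      na.strings = "")),
           daily = as.data.frame(data.table::fread(config$daily_path,
                                                   na.strings = ""))) |>
        (function(x) {
          for (col in c("lmp_date", "due_date", "end_date"))
            x$profiles[[col]] <- as.Date(x$profiles[[col]])
          x$daily$date <- as.Date(x$daily$date)
          x
        })()
    }
  })
  prep <- stage("preprocess", {
    pw <- prepare_weekly(cohort$daily, cohort$profiles,
                         metrics = config$metrics,
                         availability_threshold = config$availability_threshold,
                         baseline_min_days = config$baseline_min_days,
                         baseline_sd_floor = config$baseline_sd_floor)
    data.table::fwrite(pw$weekly_z, file.path(config$out_dir, "weekly_z.csv"))
    data.table::fwrite(pw$exclusions, file.path(config$out_dir, "exclusions.csv"))
    pw
  })
  term_ids <- prep$profiles$participant_id[prep$profiles$outcome == "term"]
  trends <- list()
  for (m in config$metrics) {
    trends[[m]] <- stage(paste0("term:", m), {
      wz <- prep$weekly_z[prep$weekly_z$participant_id %in% term_ids, ]
      sdm <- median_baseline_sd(prep$baselines, m)
      tr <- if (config$covariates)
        fit_covariate_model(wz, prep$profiles, m, df_time = config$df_time,
                            df_cov = config$df_cov, baseline_sd = sdm)
      else fit_ga_model(wz, m, df = config$df_time, baseline_sd = sdm)
      data.table::fwrite(tr$curve, file.path(config$out_dir,
                                             paste0("trend_", m, ".csv")))
      tests <- list(metric = m,
                    ga_wald = unclass(tr$ga_wald)[c("statistic", "df", "p.value")],
                    trimester_deltas = tr$trimester_deltas,
                    extremum = tr$extremum)
      if (!is.null(tr$age_wald))
        tests$age_wald <- unclass(tr$age_wald)[c("statistic", "df", "p.value")]
      if (!is.null(tr$bmi_wald))
        tests$bmi_wald <- unclass(tr$bmi_wald)[c("statistic", "df", "p.value")]
      jsonlite::write_json(tests, file.path(config$out_dir,
                                            paste0("tests_", m, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      tr
    })
  }
  losses <- list()
  n_loss <- sum(prep$profiles$outcome == "loss")
  if (n_loss >= 10L) {
    for (m in config$metrics) {
      losses[[m]] <- stage(paste0("loss:", m), {
        lr <- loss_divergence_analysis(cohort$daily, cohort$profiles, m,
                                       seed = seeds[2L], df = config$df_loss,
                                       onset_threshold_z = config$onset_threshold_z,
                                       min_coverage = config$loss_min_coverage,
                                       max_gap = config$interpolation_max_gap,
                                       availability_threshold = config$availability_threshold)
        data.table::fwrite(lr$curves, file.path(config$out_dir,
                                                paste0("loss_curves_", m, ".csv")))
        jsonlite::write_json(
          list(metric = m,
               outcome_wald = unclass(lr$outcome_wald)[c("statistic", "df", "p.value")],
               delta_28d = lr$delta_28d, delta_7d = lr$delta_7d,
               onset_day = lr$onset_day, n_pairs = lr$n_pairs),
          file.path(config$out_dir, paste0("loss_", m, ".json")),
          auto_unbox = TRUE, digits = NA)
        lr
      })
    }
  }
  manifest <- stage("manifest", {
    inputs <- c(file.path(config$out_dir, c("profiles.csv", "daily.csv")),
                config$daily_path, config$profiles_path)
    inputs <- inputs[!is.null(inputs) & file.exists(inputs)]
    mf <- list(seed = config$seed,
               package_version = as.character(utils::packageVersion("gravida")),
               config = unclass(config),
               input_md5 = as.list(tools::md5sum(inputs)),
               metrics = config$metrics)
    jsonlite::write_json(mf, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mf
  })
  invisible(list(trends = trends, losses = losses, manifest = manifest,
                 prep = prep))
}

#' Assemble summary tables from a completed pipeline run
#'
#' Reads the per-metric JSON/CSV outputs in a results directory and returns
#' one table of trajectory Wald tests, one of trimester deltas, and one of
#' pre-loss effect sizes and onsets. Missing pieces are flagged with a
#' warning, not an error.
#'
#' @param results_dir the pipeline output directory.
#' @return list of data frames: `wald`, `trimester_deltas`, `loss`.
#' @export
make_report <- function(results_dir) {
  tf <- list.files(results_dir, pattern = "^tests_.*\\.json$", full.names = TRUE)
  lf <- list.files(results_dir, pattern = "^loss_.*\\.json$", full.names = TRUE)
  tf <- sort(tf); lf <- sort(lf)
  if (!length(tf) && !length(lf))
    warning("no result files found in ", results_dir)
  wald <- deltas <- loss <- NULL
  for (f in tf) {
    x <- jsonlite::read_json(f, simplifyVector = TRUE)
    wald <- rbind(wald, data.frame(metric = x$metric,
                                   statistic = x$ga_wald$statistic,
                                   df = x$ga_wald$df, p = x$ga_wald$p.value))
    td <- as.data.frame(x$trimester_deltas)
    td$metric <- x$metric
    deltas <- rbind(deltas, td)
  }
  for (f in lf) {
    x <- jsonlite::read_json(f, simplifyVector = TRUE)
    loss <- rbind(loss, data.frame(metric = x$metric,
                                   statistic = x$outcome_wald$statistic,
                                   df = x$outcome_wald$df,
                                   p = x$outcome_wald$p.value,
                                   delta_28d = x$delta_28d,
                                   delta_7d = x$delta_7d,
                                   onset_day = x$onset_day %||% NA_integer_,
                                   n_pairs = x$n_pairs))
  }
  empty <- function() data.frame()
  list(wald = wald %||% empty(), trimester_deltas = deltas %||% empty(),
       loss = loss %||% empty())
}
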