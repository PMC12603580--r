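# Analysis 1: population trajectories of baseline-normalized weekly metrics
# across gestation for term pregnancies, fit by spline-GEE, with optional
# age/BMI moderation via tensor-product interactions.

#' Preprocess a cohort into analysis-ready weekly z-scores
#'
#' Runs the full cleaning chain: deduplication, main-sleep filtering,
#' alignment to the pregnancy timeline, the 40% availability exclusion,
#' baseline computation, weekly aggregation and baseline z-scoring.
#'
#' @param daily raw daily records.
#' @param profiles pregnancy profiles.
#' @param metrics metric columns to process.
#' @param availability_threshold see [apply_availability_filter()].
#' @param baseline_min_days,baseline_sd_floor see [compute_baseline()].
#' @return list: `weekly_z`, `baselines`, `daily` (aligned/cleaned),
#'   `profiles` (retained), `exclusions`.
#' @export
prepare_weekly <- function(daily, profiles, metrics = .all_metrics,
                           availability_threshold = 0.40,
                           baseline_min_days = 7L, baseline_sd_floor = 1e-6) {
  d <- filter_main_sleep(deduplicate(daily))
  d <- align_to_pregnancy(d, profiles)
  flt <- apply_availability_filter(d, profiles, availability_threshold)
  profiles <- flt$profiles
  d <- d[d$participant_id %in% profiles$participant_id, , drop = FALSE]
  bl <- compute_baseline(d, metrics, min_days = baseline_min_days,
                         sd_floor = baseline_sd_floor)
  wk <- weekly_aggregate(d, metrics)
  wz <- zscore_weekly(wk, bl)
  list(weekly_z = wz, baselines = bl, daily = d, profiles = profiles,
       exclusions = flt$exclusions)
}

# cohort-median baseline SD for one metric (native-unit conversion factor)
median_baseline_sd <- function(baselines, metric) {
  stats::median(baselines$sd[baselines$valid & baselines$metric == metric])
}

#' Gestational-age trajectory model for one metric
#'
#' Fits a Gaussian GEE (exchangeable working correlation) of the weekly
#' baseline z-scores on an intercept plus a `df`-degree-of-freedom B-spline
#' of gestational week, clustering by participant. Reports the joint Wald
#' test on the spline block, the fitted per-week curve with robust pointwise
#' SEs, the within-gestation extremum of the fitted curve, and mean fitted
#' deviations per trimester (in z units, and in native units when
#' `baseline_sd` is supplied).
#'
#' @param weekly_z weekly z-scored series (see [prepare_weekly()]).
#' @param metric metric to model.
#' @param df spline degrees of freedom (default 8).
#' @param degree spline polynomial degree (default cubic).
#' @param baseline_sd native units per z unit (cohort-median baseline SD);
#'   enables native-unit curves and deltas.
#' @param week_range gestational weeks entering the model. The default,
#'   week 0 onward, excludes the prepregnancy weeks: the response is already
#'   normalized to the individual prepregnancy baseline, so those weeks carry
#'   no trend information and would dilute the spline's resolution over
#'   gestation. Set to `c(-8, 56)` to model the full window.
#' @return object of class `preg_trend`.
#' @export
fit_ga_model <- function(weekly_z, metric, df = 8L, degree = 3L,
                         baseline_sd = NULL, week_range = c(0, 56)) {
  d <- weekly_z[weekly_z$metric == metric &
                  weekly_z$gestational_week >= week_range[1] &
                  weekly_z$gestational_week <= week_range[2], , drop = FALSE]
  if (!nrow(d)) stop("no weekly data for metric '", metric, "'")
  basis <- bs_basis(d$gestational_week, df = df, degree = degree)
  X <- cbind(`(Intercept)` = 1, basis)
  blocks <- list(intercept = 1L, time_spline = seq_len(df) + 1L)
  fit <- gee_fit(d$value_z, X, d$participant_id, blocks = blocks)
  ga_wald <- joint_wald(fit, "time_spline")
  trend_result(fit, basis, metric, ga_wald, d, baseline_sd,
               covariates = NULL)
}

#' Trajectory model with age and BMI moderation
#'
#' Extends the gestational-age model with B-spline main effects of maternal
#' age and prepregnancy BMI (each `df_cov` degrees of freedom) and
#' tensor-product interactions of each with the gestational-age spline. The
#' age and BMI Wald tests are joint over the main-effect and interaction
#' blocks by default (`wald = "combined"`); `wald = "interaction"` tests the
#' tensor blocks alone.
#'
#' @param weekly_z weekly z-scored series.
#' @param profiles retained profiles carrying `age` and either `bmi` or
#'   `weight_kg`/`height_m`.
#' @param metric metric to model.
#' @param df_time,df_cov spline degrees of freedom for gestational week and
#'   for the covariates.
#' @param degree spline degree.
#' @param baseline_sd native units per z unit.
#' @param wald `"combined"` or `"interaction"`.
#' @param week_range gestational weeks entering the model (see
#'   [fit_ga_model()]).
#' @return object of class `preg_trend` with `age_wald` and `bmi_wald`.
#' @export
fit_covariate_model <- function(weekly_z, profiles, metric, df_time = 8L,
                                df_cov = 3L, degree = 3L, baseline_sd = NULL,
                                wald = c("combined", "interaction"),
                                week_range = c(0, 56)) {
  wald <- match.arg(wald)
  if (!"bmi" %in% names(profiles))
    profiles$bmi <- compute_bmi(profiles$weight_kg, profiles$height_m)
  d <- weekly_z[weekly_z$metric == metric &
                  weekly_z$gestational_week >= week_range[1] &
                  weekly_z$gestational_week <= week_range[2], , drop = FALSE]
  if (!nrow(d)) stop("no weekly data for metric '", metric, "'")
  idx <- match(d$participant_id, profiles$participant_id)
  if (anyNA(idx)) stop("weekly series for participants absent from profiles")
  d$age <- profiles$age[idx]
  d$bmi <- profiles$bmi[idx]
  Tb <- bs_basis(d$gestational_week, df = df_time, degree = degree)
  Ab <- bs_basis(d$age, df = df_cov, degree = degree)
  Bb <- bs_basis(d$bmi, df = df_cov, degree = degree)
  colnames(Tb) <- paste0("t", seq_len(ncol(Tb)))
  colnames(Ab) <- paste0("a", seq_len(ncol(Ab)))
  colnames(Bb) <- paste0("b", seq_len(ncol(Bb)))
  TA <- tensor_product(Tb, Ab)
  TB <- tensor_product(Tb, Bb)
  X <- cbind(`(Intercept)` = 1, Tb, Ab, Bb, TA, TB)
  k <- cumsum(c(1L, ncol(Tb), ncol(Ab), ncol(Bb), ncol(TA), ncol(TB)))
  blocks <- list(intercept = 1L,
                 time_spline = (k[1] + 1L):k[2],
                 age_spline = (k[2] + 1L):k[3],
                 bmi_spline = (k[3] + 1L):k[4],
                 time_age_tensor = (k[4] + 1L):k[5],
                 time_bmi_tensor = (k[5] + 1L):k[6])
  fit <- gee_fit(d$value_z, X, d$participant_id, blocks = blocks)
  ga_wald <- joint_wald(fit, "time_spline")
  age_blocks <- if (wald == "combined") c("age_spline", "time_age_tensor")
                else "time_age_tensor"
  bmi_blocks <- if (wald == "combined") c("bmi_spline", "time_bmi_tensor")
                else "time_bmi_tensor"
  out <- trend_result(fit, Tb, metric, ga_wald, d, baseline_sd,
                      covariates = list(age_basis = Ab, bmi_basis = Bb,
                                        age_ref = mean(d$age),
                                        bmi_ref = mean(d$bmi)))
  out$age_wald <- joint_wald(fit, age_blocks)
  out$bmi_wald <- joint_wald(fit, bmi_blocks)
  out
}

# build the design row block for a preg_trend at given weeks / covariates
trend_design <- function(trend, weeks, age = NULL, bmi = NULL) {
  Tb <- bs_apply(weeks, trend$time_basis)
  if (is.null(trend$covariates)) return(cbind(1, Tb))
  cv <- trend$covariates
  age <- age %||% cv$age_ref
  bmi <- bmi %||% cv$bmi_ref
  Ab <- bs_apply(rep(age, length(weeks)), cv$age_basis)
  Bb <- bs_apply(rep(bmi, length(weeks)), cv$bmi_basis)
  cbind(1, Tb, Ab, Bb, tensor_product(Tb, Ab), tensor_product(Tb, Bb))
}

# shared constructor of the trend-result object
trend_result <- function(fit, time_basis, metric, ga_wald, d, baseline_sd,
                         covariates) {
  obj <- structure(list(metric = metric, fit = fit, ga_wald = ga_wald,
                        time_basis = time_basis, covariates = covariates,
                        baseline_sd = baseline_sd,
                        week_range = range(d$gestational_week),
                        n_participants = length(unique(d$participant_id))),
                   class = "preg_trend")
  wr <- obj$week_range
  weeks <- seq(ceiling(wr[1]), floor(wr[2]))
  pr <- predict(fit, trend_design(obj, weeks), se.fit = TRUE)
  curve <- data.frame(week = weeks, fitted_z = pr$fit, se_z = pr$se.fit)
  if (!is.null(baseline_sd)) {
    curve$fitted_native <- curve$fitted_z * baseline_sd
    curve$se_native <- curve$se_z * baseline_sd
  }
  obj$curve <- curve
  # extremum of |fitted z| within gestation (weeks 0..40), at the model's
  # native weekly resolution
  gw <- seq(max(0, ceiling(wr[1])), min(40, floor(wr[2])))
  fg <- predict(fit, trend_design(obj, gw))
  i <- which.max(abs(fg))
  obj$extremum <- list(week = gw[i], fitted_z = fg[i],
                       fitted_native = if (!is.null(baseline_sd))
                         fg[i] * baseline_sd else NA_real_)
  obj$trimester_deltas <- summarize_trimesters(obj, baseline_sd)
  obj
}

#' Mean fitted deviation per trimester
#'
#' Averages the fitted curve over the weeks of each trimester (T1 weeks
#' 0-13, T2 14-27, T3 28-40) and over the postpartum tail of the window
#' (weeks 41 onward), converting to native units with the cohort-median
#' baseline SD when supplied.
#'
#' @param trend a `preg_trend` object.
#' @param baseline_sd native units per z unit (optional).
#' @return data frame: phase, delta_z, and delta_native when convertible.
#' @export
summarize_trimesters <- function(trend, baseline_sd = NULL) {
  cv <- trend$curve
  phases <- list(T1 = 0:13, T2 = 14:27, T3 = 28:40,
                 post = 41:max(41, max(cv$week)))
  dz <- vapply(phases, function(w) {
    v <- cv$fitted_z[cv$week %in% w]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- data.frame(phase = names(phases), delta_z = dz)
  if (!is.null(baseline_sd)) out$delta_native <- dz * baseline_sd
  rownames(out) <- NULL
  out
}

#' Predict the fitted trajectory at chosen weeks (and covariate values)
#'
#' @param trend a `preg_trend` object.
#' @param weeks gestational weeks (within the fitted range).
#' @param age,bmi covariate values (covariate models only; defaults are the
#'   estimation-sample means).
#' @param se.fit also return robust pointwise SEs.
#' @return fitted z values, or a list `fit`/`se.fit`.
#' @export
predict_curve <- function(trend, weeks, age = NULL, bmi = NULL, se.fit = FALSE) {
  stopifnot(inherits(trend, "preg_trend"))
  predict(trend$fit, trend_design(trend, weeks, age, bmi), se.fit = se.fit)
}

#' @export
print.preg_trend <- function(x, ...) {
  cat(sprintf("Pregnancy trajectory model: %s (%d participants, weeks %g..%g)\n",
              x$metric, x$n_participants, x$week_range[1], x$week_range[2]))
  cat(sprintf("Gestational-age joint Wald: chi^2 = %.2f, df = %d, p = %.3g\n",
              x$ga_wald$statistic, x$ga_wald$df, x$ga_wald$p.value))
  if (!is.null(x$age_wald))
    cat(sprintf("Age effect joint Wald:      chi^2 = %.2f, df = %d, p = %.3g\n",
                x$age_wald$statistic, x$age_wald$df, x$age_wald$p.value))
  if (!is.null(x$bmi_wald))
    cat(sprintf("BMI effect joint Wald:      chi^2 = %.2f, df = %d, p = %.3g\n",
                x$bmi_wald$statistic, x$bmi_wald$df, x$bmi_wald$p.value))
  cat(sprintf("Extremum within gestation: week %.1f, fitted z = %.3f%s\n",
              x$extremum$week, x$extremum$fitted_z,
              if (!is.na(x$extremum$fitted_native))
                sprintf(" (%.3g native units)", x$extremum$fitted_native) else ""))
  cat("\nTrimester deltas:\n")
  print(x$trimester_deltas, row.names = FALSE)
  invisible(x)
}

#' @export
plot.preg_trend <- function(x, level = 0.95, ...) {
  cv <- x$curve
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lo <- cv$fitted_z - zc * cv$se_z
  hi <- cv$fitted_z + zc * cv$se_z
  graphics::plot(cv$week, cv$fitted_z, type = "n", ylim = range(lo, hi),
                 xlab = "Gestational week", ylab = "Deviation from baseline (z)",
                 main = paste("Fitted trajectory:", x$metric), ...)
  graphics::polygon(c(cv$week, rev(cv$week)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(cv$week, cv$fitted_z, col = "steelblue4", lwd = 2)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey50")
  invisible(x)
}
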