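# Analysis 2: matched comparison of the 28 days preceding an early pregnancy
# end (loss before 20 weeks) against gestational-age-matched term controls,
# on daily baseline z-scores, with a 3-df spline of day-relative-to-end plus
# linear outcome and outcome-by-day terms.

#' Extract the 28-day pre-end window from a daily z series
#'
#' Returns the interpolated daily z values for gestational days
#' `end_day - 27 .. end_day` inclusive (day index 0 = the end day itself; an
#' end at 7 weeks 1 day yields the window 3 weeks 2 days to 7 weeks 1 day).
#' Cases ending before gestational day 28 cannot host a full within-pregnancy
#' window and return `NULL`.
#'
#' @param zseries daily z series for one participant (columns `day_offset`,
#'   `value_z`; see [daily_zscores()]).
#' @param end_day gestational day at pregnancy end.
#' @return data frame with columns `day_rel` (-27..0) and `value_z`, or
#'   `NULL` when the window cannot be extracted.
#' @export
extract_window <- function(zseries, end_day) {
  if (end_day < 28L) return(NULL)
  days <- (end_day - 27L):end_day
  z <- zseries$value_z[match(days, zseries$day_offset)]
  data.frame(day_rel = -27:0, value_z = z)
}

#' Sample gestational-age-matched term controls
#'
#' For each loss case, draws a term pregnancy uniformly at random and checks
#' that it has at least `min_coverage` observed days within the case's
#' 28-gestational-day window; failing candidates are redrawn (up to
#' `max_attempts`). Controls are sampled without reuse while the pool lasts,
#' then with replacement.
#'
#' @param cases data frame with `participant_id` and `end_day` for each loss
#'   case.
#' @param obs_days named list: term participant id -> integer vector of day
#'   offsets with observed data for the analysis metric.
#' @param seed integer seed for the matching stream.
#' @param min_coverage minimum fraction of the 28 window days observed.
#' @param max_attempts redraw cap per case.
#' @return data frame of matched pairs: `case_id`, `control_id`, `end_day`,
#'   `window_start`, `control_coverage`.
#' @export
sample_controls <- function(cases, obs_days, seed, min_coverage = 0.40,
                            max_attempts = 50L) {
  if (!length(obs_days)) stop("empty term control pool")
  set.seed(as.integer(seed))
  pool <- names(obs_days)
  remaining <- pool
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    end_day <- cases$end_day[i]
    win <- (end_day - 27L):end_day
    chosen <- NULL
    for (att in seq_len(max_attempts)) {
      src <- if (length(remaining)) remaining else pool
      cand <- src[sample.int(length(src), 1L)]
      cov <- mean(win %in% obs_days[[cand]])
      if (cov >= min_coverage) {
        chosen <- cand
        remaining <- setdiff(remaining, cand)
        break
      }
    }
    if (is.null(chosen))
      stop("control pool exhausted for case ", cases$participant_id[i],
           " (no candidate with >= ", 100 * min_coverage,
           "% coverage in ", max_attempts, " draws)")
    out[[i]] <- data.frame(case_id = cases$participant_id[i],
                           control_id = chosen, end_day = end_day,
                           window_start = end_day - 27L,
                           control_coverage = cov)
  }
  do.call(rbind, out)
}

#' Fit the pre-loss divergence GEE for a set of matched pairs
#'
#' Models the daily z values of both pair members over the 28 days before
#' the case's pregnancy end as a `df`-df B-spline of day-relative-to-end
#' plus a linear pregnancy-outcome term (1 = loss) and a linear
#' outcome-by-day interaction, clustering by pregnancy. The outcome effect is
#' assessed by a joint Wald test on the outcome and interaction coefficients.
#' Effect sizes are the mean modeled (term - loss) difference over the full
#' 28 days and over the final 7 days.
#'
#' @param pairs matched pairs from [sample_controls()].
#' @param zseries daily z series (all participants) from [daily_zscores()].
#' @param metric metric name (labeling only).
#' @param df spline degrees of freedom for day-relative-to-end (default 3).
#' @param onset_threshold_z divergence-onset threshold passed on to
#'   [estimate_divergence_onset()].
#' @return object of class `loss_divergence`.
#' @export
fit_loss_model <- function(pairs, zseries, metric = "", df = 3L,
                           onset_threshold_z = 0.25) {
  if (nrow(pairs) < 10L) stop("need at least 10 matched pairs")
  series_split <- split(zseries[c("day_offset", "value_z")],
                        zseries$participant_id)
  rows <- vector("list", 2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (side in 1:2) {
      pid <- if (side == 1L) pairs$case_id[i] else pairs$control_id[i]
      w <- extract_window(series_split[[pid]], pairs$end_day[i])
      if (is.null(w)) next
      w$participant_id <- pid
      w$outcome <- if (side == 1L) 1 else 0
      rows[[2L * (i - 1L) + side]] <- w
    }
  }
  d <- do.call(rbind, rows)
  d <- d[!is.na(d$value_z), , drop = FALSE]
  basis <- bs_basis(d$day_rel, df = df, boundary = c(-27, 0))
  X <- cbind(`(Intercept)` = 1, basis, outcome = d$outcome,
             `outcome:day` = d$outcome * d$day_rel)
  blocks <- list(intercept = 1L, time_spline = seq_len(df) + 1L,
                 outcome = df + 2L, outcome_by_day = df + 3L)
  fit <- gee_fit(d$value_z, X, d$participant_id, blocks = blocks)
  outcome_wald <- joint_wald(fit, c("outcome", "outcome_by_day"))
  grid <- -27:0
  Bg <- bs_apply(grid, basis)
  term_curve <- drop(cbind(1, Bg, 0, 0) %*% fit$coefficients)
  loss_curve <- drop(cbind(1, Bg, 1, grid) %*% fit$coefficients)
  obj <- structure(list(metric = metric, fit = fit,
                        outcome_wald = outcome_wald,
                        n_pairs = nrow(pairs), pairs = pairs,
                        curves = data.frame(day_rel = grid, term = term_curve,
                                            loss = loss_curve)),
                   class = "loss_divergence")
  es <- effect_sizes(obj)
  obj$delta_28d <- es[["delta_28d"]]
  obj$delta_7d <- es[["delta_7d"]]
  obj$onset_day <- estimate_divergence_onset(obj, q = onset_threshold_z)
  obj
}

#' Pre-loss effect sizes
#'
#' Mean modeled (term - loss) difference in z units over the 28 days before
#' pregnancy end and over the final 7 days, computed from the fitted curves.
#'
#' @param result a `loss_divergence` object.
#' @return named numeric vector `delta_28d`, `delta_7d`.
#' @export
effect_sizes <- function(result) {
  cv <- result$curves
  diff <- cv$term - cv$loss
  c(delta_28d = mean(diff),
    delta_7d = mean(diff[cv$day_rel >= -6]))
}

#' Estimated divergence onset before pregnancy end
#'
#' The most negative day `d*` such that the fitted (loss - term) difference
#' stays below `-q` z units on every day from `d*` through the end day.
#' Returns `NA` when no day qualifies.
#'
#' @param result a `loss_divergence` object.
#' @param q sustained-divergence threshold in z units (default 0.25).
#' @return onset in days before the end (negative integer), or `NA`.
#' @export
estimate_divergence_onset <- function(result, q = 0.25) {
  cv <- result$curves
  below <- (cv$loss - cv$term) < -q
  # sustained through day 0: longest all-TRUE suffix
  if (!below[length(below)]) return(NA_integer_)
  first_ok <- max(c(0L, which(!below))) + 1L
  cv$day_rel[first_ok]
}

#' @export
print.loss_divergence <- function(x, ...) {
  cat(sprintf("Pre-loss divergence model: %s (%d matched pairs)\n",
              x$metric, x$n_pairs))
  cat(sprintf("Outcome joint Wald: chi^2 = %.2f, df = %d, p = %.3g\n",
              x$outcome_wald$statistic, x$outcome_wald$df,
              x$outcome_wald$p.value))
  cat(sprintf("Mean (term - loss) difference: %.3f z over 28 d, %.3f z over final 7 d\n",
              x$delta_28d, x$delta_7d))
  if (is.na(x$onset_day)) cat("No sustained divergence detected\n")
  else cat(sprintf("Estimated divergence onset: day %d (%.2f weeks before end)\n",
                   x$onset_day, -x$onset_day / 7))
  invisible(x)
}

#' @export
plot.loss_divergence <- function(x, ...) {
  cv <- x$curves
  graphics::plot(cv$day_rel, cv$term, type = "l", col = "forestgreen", lwd = 2,
                 ylim = range(cv$term, cv$loss),
                 xlab = "Day relative to pregnancy end",
                 ylab = "Deviation from baseline (z)",
                 main = paste("Pre-loss divergence:", x$metric), ...)
  graphics::lines(cv$day_rel, cv$loss, col = "firebrick", lwd = 2)
  if (!is.na(x$onset_day)) graphics::abline(v = x$onset_day, lty = 3)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::legend("bottomleft", c("term", "loss"), lwd = 2,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}

#' End-to-end pre-loss divergence analysis
#'
#' Runs the full chain on a raw cohort: cleaning, alignment, availability
#' filtering, baseline z-scoring with gap interpolation, case selection
#' (loss pregnancies ending at gestational day 28 or later with a valid
#' baseline), gestational-age-matched control sampling, and the divergence
#' GEE for one metric.
#'
#' @param daily,profiles raw cohort tables.
#' @param metric metric to analyze.
#' @param seed seed for the control-matching stream.
#' @param n_pairs cap on the number of matched pairs (first cases in
#'   participant order; `NULL` = all eligible cases).
#' @param df,onset_threshold_z,min_coverage,max_gap tuning parameters (see
#'   [fit_loss_model()], [estimate_divergence_onset()], [sample_controls()],
#'   [interpolate_daily()]).
#' @param availability_threshold see [apply_availability_filter()].
#' @return a `loss_divergence` object.
#' @export
loss_divergence_analysis <- function(daily, profiles, metric, seed,
                                     n_pairs = NULL, df = 3L,
                                     onset_threshold_z = 0.25,
                                     min_coverage = 0.40, max_gap = 7L,
                                     availability_threshold = 0.40) {
  d <- filter_main_sleep(deduplicate(daily))
  d <- align_to_pregnancy(d, profiles)
  flt <- apply_availability_filter(d, profiles, availability_threshold)
  profiles <- flt$profiles
  d <- d[d$participant_id %in% profiles$participant_id, , drop = FALSE]
  bl <- compute_baseline(d, metric)
  zs <- daily_zscores(d, bl, metric, max_gap = max_gap)
  valid_ids <- unique(zs$participant_id)

  start <- infer_pregnancy_start(profiles$lmp_date, profiles$due_date)
  end_day <- as.integer(profiles$end_date - start)
  is_case <- profiles$outcome == "loss" & end_day >= 28L &
    profiles$participant_id %in% valid_ids
  cases <- data.frame(participant_id = profiles$participant_id[is_case],
                      end_day = end_day[is_case])
  cases <- cases[order(cases$participant_id), , drop = FALSE]
  if (!is.null(n_pairs)) cases <- utils::head(cases, n_pairs)
  if (nrow(cases) < 10L) stop("fewer than 10 eligible loss cases")

  term_ids <- profiles$participant_id[profiles$outcome == "term" &
                                        profiles$participant_id %in% valid_ids]
  obs <- d[d$participant_id %in% term_ids & !is.na(d[[metric]]),
           c("participant_id", "day_offset")]
  obs_days <- split(obs$day_offset, obs$participant_id)
  pairs <- sample_controls(cases, obs_days, seed = seed,
                           min_coverage = min_coverage)
  fit_loss_model(pairs, zs, metric = metric, df = df,
                 onset_threshold_z = onset_threshold_z)
}
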