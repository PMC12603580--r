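# Cleaning and normalization: deduplication, main-sleep filtering, the 40%
# availability exclusion, weekly aggregation, individual prepregnancy
# baseline z-scoring, and gap interpolation for the daily pre-loss analysis.

.datatable.aware <- TRUE

#' Remove duplicate participant-days
#'
#' Keeps at most one record per (participant, date); when duplicates conflict
#' the last-seen record wins and a warning is emitted.
#'
#' @param daily daily record data frame.
#' @return deduplicated data frame.
#' @export
deduplicate <- function(daily) {
  key <- paste(daily$participant_id, daily$date)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conflicting <- !duplicated(daily, fromLast = TRUE) & dup
    if (any(conflicting))
      warning(sum(conflicting), " conflicting duplicate record(s); keeping the last seen")
  }
  out <- daily[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Blank sleep-period metrics outside main nocturnal sleep
#'
#' Sleep, temperature and cardiorespiratory metrics are measured during the
#' main nocturnal sleep only; records flagged as naps or diurnal sleep keep
#' their step counts but lose those fields.
#'
#' @param daily daily record data frame with an `is_main_sleep` flag.
#' @return data frame with non-main-sleep physiological fields set to `NA`.
#' @export
filter_main_sleep <- function(daily) {
  if (!"is_main_sleep" %in% names(daily)) stop("records carry no is_main_sleep flag")
  out <- daily
  drop <- !out$is_main_sleep
  for (m in intersect(.sleep_metrics, names(out))) out[[m]][drop] <- NA
  out
}

#' Apply the 40% data-availability exclusion
#'
#' A pregnancy is retained iff the fraction of days with any record is at
#' least `threshold` in the prepregnancy window (days -56..-1) and in every
#' trimester the pregnancy overlaps. A trimester's denominator is the number
#' of days between its start and `min(trimester end, pregnancy end)`;
#' trimesters the pregnancy never reaches are not evaluated.
#'
#' @param daily aligned daily records (see [align_to_pregnancy()]).
#' @param profiles pregnancy profiles.
#' @param threshold minimum availability fraction (default 0.40).
#' @return list with `profiles` (retained rows) and `exclusions` (data frame
#'   of participant, window, coverage, reason for every failing window).
#' @export
apply_availability_filter <- function(daily, profiles, threshold = 0.40) {
  start <- infer_pregnancy_start(profiles$lmp_date, profiles$due_date)
  end_day <- as.integer(profiles$end_date - start)
  counts <- lapply(.trimester_windows, function(w) {
    inw <- daily$day_offset >= w[1] & daily$day_offset <= w[2]
    tab <- table(daily$participant_id[inw])
    as.integer(tab[match(profiles$participant_id, names(tab))])
  })
  excl <- list()
  ok <- rep(TRUE, nrow(profiles))
  for (win in names(.trimester_windows)) {
    w <- .trimester_windows[[win]]
    denom <- if (win == "pre") rep(56L, nrow(profiles))
             else pmin(w[2], end_day) - w[1] + 1L
    evaluated <- denom >= 1L
    have <- counts[[win]]
    have[is.na(have)] <- 0L
    cov <- ifelse(evaluated, have / pmax(denom, 1L), NA)
    fail <- evaluated & cov < threshold
    ok <- ok & !fail
    if (any(fail))
      excl[[win]] <- data.frame(participant_id = profiles$participant_id[fail],
                                window = win, coverage = cov[fail],
                                reason = sprintf("availability < %.0f%% in %s",
                                                 100 * threshold, win))
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(), window = character(),
               coverage = numeric(), reason = character())
  rownames(exclusions) <- NULL
  list(profiles = profiles[ok, , drop = FALSE], exclusions = exclusions)
}

#' Individual prepregnancy baseline statistics
#'
#' Mean and sample SD of each metric over gestational days -28..-1 (the
#' 4 weeks preceding the estimated pregnancy start). A participant-metric
#' baseline is flagged invalid when fewer than `min_days` days contribute or
#' the SD falls below `sd_floor` (z-scores would be ill-defined).
#'
#' @param daily aligned daily records.
#' @param metrics metric columns to summarize (default: all).
#' @param min_days minimum contributing days (default 7).
#' @param sd_floor minimum SD in native units (default 1e-6).
#' @return data frame: participant_id, metric, mean, sd, n_days, valid.
#' @export
compute_baseline <- function(daily, metrics = .all_metrics, min_days = 7L,
                             sd_floor = 1e-6) {
  metrics <- intersect(metrics, names(daily))
  d <- data.table::as.data.table(daily)[day_offset >= -28L & day_offset <= -1L]
  for (m in metrics) d[, (m) := as.numeric(get(m))]
  long <- data.table::melt(d, id.vars = "participant_id",
                           measure.vars = metrics, variable.name = "metric",
                           variable.factor = FALSE)
  bl <- long[!is.na(value),
             .(mean = mean(value), sd = stats::sd(value), n_days = .N),
             by = .(participant_id, metric)]
  bl[, valid := n_days >= min_days & !is.na(sd) & sd >= sd_floor]
  as.data.frame(bl)
}

#' Weekly aggregation of daily records
#'
#' Arithmetic mean of the available days within each gestational-week bin
#' (week w = day offsets 7w..7w+6); weeks without data yield no row (no
#' weekly-level imputation).
#'
#' @param daily aligned, deduplicated daily records.
#' @param metrics metric columns to aggregate.
#' @return data frame: participant_id, metric, gestational_week, value_raw.
#' @export
weekly_aggregate <- function(daily, metrics = .all_metrics) {
  metrics <- intersect(metrics, names(daily))
  d <- data.table::as.data.table(daily)
  for (m in metrics) d[, (m) := as.numeric(get(m))]
  long <- data.table::melt(d, id.vars = c("participant_id", "gestational_week"),
                           measure.vars = metrics, variable.name = "metric",
                           variable.factor = FALSE)
  wk <- long[!is.na(value), .(value_raw = mean(value)),
             by = .(participant_id, metric, gestational_week)]
  data.table::setorder(wk, participant_id, metric, gestational_week)
  as.data.frame(wk)
}

#' Z-score weekly values against individual prepregnancy baselines
#'
#' `value_z = (value_raw - baseline mean) / baseline sd`. Participant-metric
#' series with an invalid baseline are dropped from that metric's analysis.
#'
#' @param weekly output of [weekly_aggregate()].
#' @param baselines output of [compute_baseline()].
#' @return `weekly` with a `value_z` column, restricted to valid baselines.
#' @export
zscore_weekly <- function(weekly, baselines) {
  bl <- baselines[baselines$valid, c("participant_id", "metric", "mean", "sd")]
  out <- merge(weekly, bl, by = c("participant_id", "metric"))
  out$value_z <- (out$value_raw - out$mean) / out$sd
  out$mean <- NULL; out$sd <- NULL
  out[order(out$participant_id, out$metric, out$gestational_week), , drop = FALSE]
}

#' Linear interpolation of interior gaps in a daily series
#'
#' Fills interior missing days linearly between the nearest observed
#' neighbours; leading and trailing gaps stay missing, as do gaps longer than
#' `max_gap` days (interpolation is only trusted across short interruptions).
#'
#' @param day integer day indices of the observed series (need not be
#'   contiguous; the output covers the full `min(day)..max(day)` grid).
#' @param value values on `day` (may contain `NA`).
#' @param max_gap longest run of consecutive missing days that is filled.
#' @return data frame with columns `day` (full grid) and `value`.
#' @export
interpolate_daily <- function(day, value, max_gap = 7L) {
  stopifnot(length(day) == length(value))
  o <- order(day)
  day <- day[o]; value <- value[o]
  grid <- seq(min(day), max(day))
  v <- rep(NA_real_, length(grid))
  v[match(day, grid)] <- value
  obs <- which(!is.na(v))
  if (length(obs) >= 2L) {
    filled <- stats::approx(grid[obs], v[obs], xout = grid)$y
    runs <- rle(is.na(v))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep_fill <- rep(FALSE, length(grid))
    for (k in seq_along(runs$lengths)) {
      if (runs$values[k] && runs$lengths[k] <= max_gap &&
          starts[k] > obs[1L] && ends[k] < obs[length(obs)])
        keep_fill[starts[k]:ends[k]] <- TRUE
    }
    v[keep_fill] <- filled[keep_fill]
  }
  data.frame(day = grid, value = v)
}

#' Daily z-scored, gap-interpolated series for one metric
#'
#' Z-scores the daily values of `metric` against each participant's
#' prepregnancy baseline and fills interior gaps up to `max_gap` days by
#' linear interpolation (used by the pre-loss divergence analysis, which
#' works at daily rather than weekly resolution).
#'
#' @param daily aligned daily records.
#' @param baselines output of [compute_baseline()].
#' @param metric metric name.
#' @param max_gap see [interpolate_daily()].
#' @return data frame: participant_id, day_offset, value_z (full per-subject
#'   day grid; participants with invalid baselines are dropped).
#' @export
daily_zscores <- function(daily, baselines, metric, max_gap = 7L) {
  bl <- baselines[baselines$valid & baselines$metric == metric, ]
  d <- daily[daily$participant_id %in% bl$participant_id &
               !is.na(daily[[metric]]),
             c("participant_id", "day_offset", metric)]
  idx <- match(d$participant_id, bl$participant_id)
  z <- (d[[metric]] - bl$mean[idx]) / bl$sd[idx]
  dt <- data.table::data.table(participant_id = d$participant_id,
                               day_offset = d$day_offset, z = z)
  out <- dt[, {
    g <- interpolate_daily(day_offset, z, max_gap = max_gap)
    list(day_offset = g$day, value_z = g$value)
  }, by = participant_id]
  as.data.frame(out)
}
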