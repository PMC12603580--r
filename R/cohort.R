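# Seeded synthetic-cohort generator: pregnancy profiles plus daily wearable
# records with the statistical structure the analyses assume (individual
# baselines, a common gestational-week mean curve, subject random intercepts,
# independent daily noise, missing days, and a pre-loss divergence).

#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions the package's analyses assume:
#' cohort age 32.2 (SD 4.5) years and BMI 25.3 (SD 5.4) kg/m^2, outcome mix
#' term/preterm/loss of 5039/324/4955 out of 10318, and a due date recorded
#' for 49.3% of pregnancies (the rest contribute only the reported last
#' menstrual period). Baseline levels and noise scales are typical
#' ring-wearable values; see the package vignette for their rationale.
#'
#' @param n_pregnancies number of pregnancies.
#' @param outcome_proportions named fractions for `term`, `preterm`, `loss`
#'   (must sum to 1).
#' @param age_mean,age_sd,bmi_mean,bmi_sd demographic distribution.
#' @param missing_day_rate probability a participant-day record is absent.
#' @param nap_rate probability a recorded day's sleep episode is not the main
#'   nocturnal sleep.
#' @param baseline_levels named native-unit prepregnancy levels per metric.
#' @param random_intercept_sd named per-metric SD of the subject-level shift.
#' @param residual_sd named per-metric SD of independent daily noise.
#' @param due_date_known_fraction share of pregnancies with a recorded
#'   expected due date.
#' @param loss_divergence_onset_days days before the end of a loss pregnancy
#'   at which trajectories start ramping away from the term template.
#' @param postpartum_days days of follow-up recorded after pregnancy end.
#' @param seed integer seed fixing the whole cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_pregnancies = 500L,
                          outcome_proportions = c(term = 5039, preterm = 324,
                                                  loss = 4955) / 10318,
                          age_mean = 32.2, age_sd = 4.5,
                          bmi_mean = 25.3, bmi_sd = 5.4,
                          missing_day_rate = 0.2,
                          nap_rate = 0.02,
                          baseline_levels = c(time_asleep = 7.2, time_awake = 0.8,
                                              deep_pct = 20, rem_pct = 25,
                                              temp_peak = 36.5, hr = 63, hrv = 45,
                                              rr = 14, steps = 9000),
                          random_intercept_sd = c(time_asleep = 0.5, time_awake = 0.15,
                                                  deep_pct = 3, rem_pct = 3,
                                                  temp_peak = 0.3, hr = 5, hrv = 12,
                                                  rr = 1, steps = 2500),
                          residual_sd = c(time_asleep = 0.8, time_awake = 0.25,
                                          deep_pct = 4, rem_pct = 4,
                                          temp_peak = 0.25, hr = 2.5, hrv = 8,
                                          rr = 0.8, steps = 3000),
                          due_date_known_fraction = 0.493,
                          loss_divergence_onset_days = 14L,
                          postpartum_days = 112L,
                          seed = 1L) {
  stopifnot(n_pregnancies >= 1L)
  if (!setequal(names(outcome_proportions), c("term", "preterm", "loss")))
    stop("outcome_proportions must be named 'term', 'preterm', 'loss'")
  if (abs(sum(outcome_proportions) - 1) > 1e-9)
    stop("outcome proportions must sum to 1")
  rates <- c(missing_day_rate, nap_rate, due_date_known_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  for (nm in .generated_metrics) {
    if (is.na(baseline_levels[nm]) || is.na(random_intercept_sd[nm]) ||
        is.na(residual_sd[nm]))
      stop("baseline level and noise SDs required for metric '", nm, "'")
  }
  structure(list(n_pregnancies = as.integer(n_pregnancies),
                 outcome_proportions = outcome_proportions[c("term", "preterm", "loss")],
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 missing_day_rate = missing_day_rate, nap_rate = nap_rate,
                 baseline_levels = baseline_levels,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 due_date_known_fraction = due_date_known_fraction,
                 loss_divergence_onset_days = as.integer(loss_divergence_onset_days),
                 postpartum_days = as.integer(postpartum_days),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d pregnancies (term %.3f / preterm %.3f / loss %.3f), seed %d\n",
              x$n_pregnancies, x$outcome_proportions["term"],
              x$outcome_proportions["preterm"], x$outcome_proportions["loss"],
              x$seed))
  invisible(x)
}

#' Generate a synthetic cohort of pregnancies and daily wearable records
#'
#' For each pregnancy the outcome is drawn from the configured proportions;
#' the gestational age at pregnancy end is uniform over weeks 4-20 for
#' losses, 28-36 for preterm and 37-42 for term births. Each daily metric is
#' the participant's baseline level plus the template deviation at that
#' gestational week, a subject random intercept, and independent Gaussian
#' daily noise; steps are rounded and floored at zero. Loss pregnancies
#' follow the term template until `loss_divergence_onset_days` before their
#' end, then ramp linearly to the template's `loss_end_deviation`, and revert
#' to baseline after the end. Records span day -56 (8 weeks prepregnancy)
#' through `min(end + postpartum_days, day 391)`; days are dropped
#' independently at `missing_day_rate`. `time_in_bed` is the sum of time
#' asleep and awake; `light_pct` completes the sleep stages to 100%.
#'
#' @param config a [cohort_config()].
#' @param templates named list of [trajectory_template()]s covering every
#'   generated metric (default [default_templates()]).
#' @return list with data frames `profiles` (one row per pregnancy) and
#'   `daily` (one row per recorded participant-day).
#' @export
generate_cohort <- function(config, templates = default_templates()) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(templates) == 0L) stop("empty template set")
  missing_t <- setdiff(.generated_metrics, names(templates))
  if (length(missing_t))
    stop("templates missing for metric(s): ", paste(missing_t, collapse = ", "))
  set.seed(config$seed)
  n <- config$n_pregnancies
  pid <- sprintf("P%05d", seq_len(n))

  outcome <- sample(names(config$outcome_proportions), n, replace = TRUE,
                    prob = config$outcome_proportions)
  end_ga <- integer(n)
  end_ga[outcome == "loss"]    <- sample(28:139, sum(outcome == "loss"), TRUE)
  end_ga[outcome == "preterm"] <- sample(196:258, sum(outcome == "preterm"), TRUE)
  end_ga[outcome == "term"]    <- sample(259:294, sum(outcome == "term"), TRUE)

  start <- as.Date("2023-05-01") + sample.int(400L, n, TRUE) - 1L
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 51)
  bmi <- pmin(pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 15), 60)
  height <- pmin(pmax(stats::rnorm(n, 1.65, 0.07), 1.40), 1.95)
  weight <- round(bmi * height^2, 1)
  due_known <- stats::runif(n) < config$due_date_known_fraction
  due <- start + 280L
  due[!due_known] <- NA

  profiles <- data.frame(
    participant_id = pid, age = round(age, 1), height_m = round(height, 2),
    weight_kg = weight, lmp_date = start, due_date = due,
    end_date = start + end_ga, outcome = outcome,
    stringsAsFactors = FALSE)

  # expand participant-days
  last_day <- pmin(end_ga + config$postpartum_days, 391L)
  n_days <- last_day + 57L
  row_p <- rep.int(seq_len(n), n_days)
  day <- sequence(n_days) - 57L
  wk <- day / 7
  is_loss <- outcome[row_p] == "loss"
  end_row <- end_ga[row_p]
  onset <- config$loss_divergence_onset_days
  post_loss <- is_loss & day > end_row
  ramp <- ifelse(is_loss & day > end_row - onset & day <= end_row,
                 (day - (end_row - onset)) / onset, 0)

  vals <- list()
  for (m in .generated_metrics) {
    tpl <- templates[[m]]
    dev <- evaluate_template(tpl, pmin(pmax(wk, tpl$anchors[1, "week"]),
                                       tpl$anchors[nrow(tpl$anchors), "week"]),
                             age = age[row_p], bmi = bmi[row_p])
    dev <- dev * (!post_loss) + tpl$loss_end_deviation * ramp
    b <- stats::rnorm(n, 0, config$random_intercept_sd[m])
    x <- config$baseline_levels[m] + dev + b[row_p] +
      stats::rnorm(length(day), 0, config$residual_sd[m])
    vals[[m]] <- x
  }
  vals$time_asleep <- pmax(vals$time_asleep, 0.5)
  vals$time_awake <- pmax(vals$time_awake, 0)
  vals$deep_pct <- pmin(pmax(vals$deep_pct, 0.5), 60)
  vals$rem_pct <- pmin(pmax(vals$rem_pct, 0.5), 60)
  vals$steps <- pmax(round(vals$steps), 0)
  vals$temp_peak <- pmax(vals$temp_peak, 30)
  vals$hr <- pmax(vals$hr, 30)
  vals$hrv <- pmax(vals$hrv, 2)
  vals$rr <- pmax(vals$rr, 6)

  daily <- data.frame(
    participant_id = pid[row_p],
    date = start[row_p] + day,
    time_in_bed = vals$time_asleep + vals$time_awake,
    time_asleep = vals$time_asleep,
    time_awake = vals$time_awake,
    light_pct = 100 - vals$deep_pct - vals$rem_pct,
    deep_pct = vals$deep_pct,
    rem_pct = vals$rem_pct,
    temp_peak = vals$temp_peak,
    hr = vals$hr,
    hrv = vals$hrv,
    rr = vals$rr,
    steps = as.integer(vals$steps),
    is_main_sleep = stats::runif(length(day)) >= config$nap_rate,
    stringsAsFactors = FALSE)

  keep <- stats::runif(nrow(daily)) >= config$missing_day_rate
  daily <- daily[keep, , drop = FALSE]
  rownames(daily) <- NULL
  list(profiles = profiles, daily = daily)
}

#' Write a cohort to delimited text files
#'
#' Writes `profiles.csv` and `daily.csv` into `directory`. Dates are
#' ISO-8601, floats are written at full round-trip precision and missing
#' values as empty fields, so [read_cohort()] reproduces the values exactly.
#'
#' @param profiles,daily data frames as returned by [generate_cohort()].
#' @param directory output directory (created if absent).
#' @return the two file paths, invisibly.
#' @export
write_cohort <- function(profiles, daily, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  fp <- file.path(directory, "profiles.csv")
  fd <- file.path(directory, "daily.csv")
  data.table::fwrite(profiles, fp, na = "")
  data.table::fwrite(daily, fd, na = "")
  invisible(c(profiles = fp, daily = fd))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `profiles.csv` and `daily.csv`.
#' @return list with data frames `profiles` and `daily`.
#' @export
read_cohort <- function(directory) {
  fp <- file.path(directory, "profiles.csv")
  fd <- file.path(directory, "daily.csv")
  if (!file.exists(fp) || !file.exists(fd))
    stop("profiles.csv / daily.csv not found in ", directory)
  profiles <- as.data.frame(data.table::fread(fp, na.strings = ""))
  daily <- as.data.frame(data.table::fread(fd, na.strings = ""))
  for (col in c("lmp_date", "due_date", "end_date"))
    if (col %in% names(profiles)) profiles[[col]] <- as.Date(profiles[[col]])
  if ("date" %in% names(daily)) daily$date <- as.Date(daily$date)
  if ("is_main_sleep" %in% names(daily))
    daily$is_main_sleep <- as.logical(daily$is_main_sleep)
  list(profiles = profiles, daily = daily)
}
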