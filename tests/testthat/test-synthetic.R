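test_that("generation is deterministic under a fixed seed", {
  a <- small_cohort(n = 15L, seed = 5L,
                    proportions = c(term = 0.5, preterm = 0.1, loss = 0.4))
  b <- small_cohort(n = 15L, seed = 5L,
                    proportions = c(term = 0.5, preterm = 0.1, loss = 0.4))
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$daily, b$daily)
  c2 <- small_cohort(n = 15L, seed = 6L,
                     proportions = c(term = 0.5, preterm = 0.1, loss = 0.4))
  expect_false(identical(a$daily, c2$daily))
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(cohort_config(outcome_proportions = c(term = 0.6, loss = 0.4)),
               "named")
  expect_error(cohort_config(outcome_proportions =
                               c(term = 0.6, preterm = 0.3, loss = 0.3)),
               "sum to 1")
  expect_error(cohort_config(missing_day_rate = 1.4), "rates")
  expect_error(cohort_config(baseline_levels = c(hr = 60)), "required for metric")
  expect_error(generate_cohort(cohort_config(), templates = list()), "empty")
})

test_that("template construction and evaluation are piecewise linear", {
  t <- trajectory_template("hr", rbind(c(-8, 0), c(0, 0), c(2, 0.3), c(6, 0.1)))
  expect_equal(evaluate_template(t, 1), 0.15)   # midpoint of a segment
  expect_equal(evaluate_template(t, c(-8, 0, 2, 6)), c(0, 0, 0.3, 0.1))
  expect_error(evaluate_template(t, 7), "outside")
  expect_error(trajectory_template("hr", rbind(c(0, 0), c(0, 1))),
               "strictly increasing")
  expect_error(trajectory_template("hr", rbind(c(1, 0), c(2, 1))),
               "at or before week 0")
  expect_error(trajectory_template("hr", rbind(c(-8, 0.2), c(2, 1))),
               "must be 0")
})

test_that("age/BMI modifiers act only from week 0 onward", {
  t <- trajectory_template("hr", rbind(c(-8, 0), c(40, 0)),
                           age_modifier = 0.01, bmi_modifier = -0.02)
  expect_equal(evaluate_template(t, -4, age = 42.2, bmi = 25.3), 0)
  expect_equal(evaluate_template(t, 4, age = 42.2, bmi = 25.3), 0.1)
  expect_equal(evaluate_template(t, 4, age = 32.2, bmi = 30.3), -0.1)
})

test_that("default templates hit their landmark anchors", {
  tpl <- default_templates()
  expect_equal(evaluate_template(tpl$temp_peak, 9), 0.3)
  expect_equal(evaluate_template(tpl$hr, 32), 10)
  expect_equal(evaluate_template(tpl$hrv, 32), -16.5)
  expect_equal(evaluate_template(tpl$steps, 8), -2000)
  expect_equal(evaluate_template(tpl$time_in_bed, 9), 0.5)  # +30 min
  expect_equal(evaluate_template(tpl$time_asleep, 9) +
                 evaluate_template(tpl$time_awake, 9),
               evaluate_template(tpl$time_in_bed, 9))
  expect_equal(tpl$time_in_bed$loss_end_deviation, -0.85)
  # every template is anchored at zero deviation prepregnancy
  for (t in tpl) expect_equal(evaluate_template(t, t$anchors[1, "week"]), 0)
})

test_that("noise-free trajectories follow the templates exactly", {
  ch <- noiseless_cohort(n = 4L, seed = 2L)
  tpl <- default_templates()
  p <- ch$profiles[1, ]
  d <- ch$daily[ch$daily$participant_id == p$participant_id, ]
  d$day <- as.integer(d$date - p$lmp_date)
  # prepregnancy days sit at the baseline level (zero deviation)
  pre <- d[d$day < 0, ]
  expect_equal(pre$hr, rep(63, nrow(pre)), tolerance = 1e-6)
  expect_equal(pre$time_in_bed, rep(8, nrow(pre)), tolerance = 1e-6)
  # gestational days follow baseline + template(week), incl. age/BMI modifiers
  for (day in c(0L, 63L, 224L)) {
    row <- d[d$day == day, ]
    expect_equal(row$hr,
                 63 + evaluate_template(tpl$hr, day / 7,
                                        age = p$age,
                                        bmi = p$weight_kg / p$height_m^2),
                 tolerance = 1e-6)
  }
  expect_equal(d$time_in_bed[d$day == 63], 8.5, tolerance = 1e-6)
})

test_that("loss trajectories ramp to the end deviation and revert after", {
  ch <- noiseless_cohort(n = 12L, seed = 3L,
                         proportions = c(term = 0, preterm = 0, loss = 1))
  pr <- ch$profiles
  pr$end <- as.integer(pr$end_date - pr$lmp_date)
  p <- pr[pr$end >= 60, ][1, ]
  d <- ch$daily[ch$daily$participant_id == p$participant_id, ]
  d$day <- as.integer(d$date - p$lmp_date)
  tpl <- default_templates()$time_in_bed
  age <- p$age; bmi <- p$weight_kg / p$height_m^2
  tv <- function(day) 8 + evaluate_template(tpl, day / 7, age = age, bmi = bmi)
  # before the 14-day onset: pure template
  expect_equal(d$time_in_bed[d$day == p$end - 14], tv(p$end - 14),
               tolerance = 1e-6)
  # midway through the ramp: template + half the end deviation
  expect_equal(d$time_in_bed[d$day == p$end - 7], tv(p$end - 7) - 0.85 * 0.5,
               tolerance = 1e-6)
  # at the end day: template + full end deviation
  expect_equal(d$time_in_bed[d$day == p$end], tv(p$end) - 0.85,
               tolerance = 1e-6)
  # after the end: reversion to baseline
  expect_equal(d$time_in_bed[d$day == p$end + 10], 8, tolerance = 1e-6)
})

test_that("record invariants hold: sums, rounding, dates, naps", {
  ch <- small_cohort(n = 25L, seed = 8L,
                     proportions = c(term = 0.6, preterm = 0.1, loss = 0.3))
  d <- ch$daily
  expect_equal(d$time_in_bed, d$time_asleep + d$time_awake, tolerance = 1e-12)
  expect_equal(d$light_pct + d$deep_pct + d$rem_pct, rep(100, nrow(d)),
               tolerance = 1e-12)
  expect_true(is.integer(d$steps))
  expect_true(all(d$steps >= 0))
  expect_true(all(d$time_awake >= 0))
  expect_true(is.logical(d$is_main_sleep))
  # one row per participant-day
  expect_false(any(duplicated(paste(d$participant_id, d$date))))
})

test_that("full-record cohorts have the documented span", {
  ch <- small_cohort(n = 6L, seed = 9L, missing_day_rate = 0, nap_rate = 0)
  pr <- ch$profiles
  end <- as.integer(pr$end_date - pr$lmp_date)
  expected <- sum(pmin(end + 112L, 391L) + 57L)
  expect_equal(nrow(ch$daily), expected)
  first_days <- tapply(as.integer(ch$daily$date - pr$lmp_date[
    match(ch$daily$participant_id, pr$participant_id)]),
    ch$daily$participant_id, min)
  expect_true(all(first_days == -56L))
})

test_that("cohort-level distributions match the configuration", {
  ch <- small_cohort(n = 1000L, seed = 10L,
                     proportions = c(term = 5039, preterm = 324,
                                     loss = 4955) / 10318)
  pr <- ch$profiles
  tab <- table(pr$outcome)
  expect_gt(tab[["term"]], 1000 * 0.488 - 4 * sqrt(1000 * 0.25))
  expect_lt(tab[["term"]], 1000 * 0.488 + 4 * sqrt(1000 * 0.25))
  expect_lt(abs(mean(pr$age) - 32.2), 0.5)
  expect_lt(abs(mean(!is.na(pr$due_date)) - 0.493), 0.06)
  end <- as.integer(pr$end_date - pr$lmp_date)
  expect_true(all(end[pr$outcome == "loss"] >= 28 & end[pr$outcome == "loss"] <= 139))
  expect_true(all(end[pr$outcome == "term"] >= 259 & end[pr$outcome == "term"] <= 294))
})

test_that("within-subject correlation matches s^2 / (s^2 + r^2)", {
  ch <- small_cohort(n = 150L, seed = 20L)
  pr <- ch$profiles
  d <- ch$daily
  d$day <- as.integer(d$date - pr$lmp_date[match(d$participant_id,
                                                 pr$participant_id)])
  pre <- d[d$day < 0 & d$is_main_sleep, ]  # flat prepregnancy segment
  f <- gee_fit(pre$temp_peak, matrix(1, nrow(pre)), pre$participant_id)
  icc_true <- 0.3^2 / (0.3^2 + 0.25^2)
  expect_lt(abs(f$alpha - icc_true), 0.05)
  # exchangeability: lag-1 and lag-10 within-subject correlations agree
  pre$dev <- pre$temp_peak - ave(pre$temp_peak, pre$participant_id)
  lagcor <- function(k) {
    m <- merge(pre[c("participant_id", "day", "dev")],
               transform(pre[c("participant_id", "day", "dev")], day = day + k),
               by = c("participant_id", "day"))
    cor(m$dev.x, m$dev.y)
  }
  expect_lt(abs(lagcor(1) - lagcor(10)), 0.05)
})

test_that("cohorts round-trip through CSV exactly", {
  ch <- small_cohort(n = 10L, seed = 21L,
                     proportions = c(term = 0.5, preterm = 0, loss = 0.5))
  dir <- tempfile(); dir.create(dir)
  write_cohort(ch$profiles, ch$daily, dir)
  expect_true(all(file.exists(file.path(dir, c("profiles.csv", "daily.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$profiles, ch$profiles)
  expect_equal(back$daily, ch$daily)
  expect_s3_class(back$profiles$due_date, "Date")
})
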