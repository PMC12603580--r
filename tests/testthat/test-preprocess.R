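test_that("deduplication keeps the last record and warns on conflicts", {
  d <- data.frame(participant_id = c("P1", "P1", "P1", "P2"),
                  date = as.Date(c("2024-01-01", "2024-01-01",
                                   "2024-01-02", "2024-01-01")),
                  hr = c(60, 65, 70, 55), stringsAsFactors = FALSE)
  expect_warning(out <- deduplicate(d), "conflicting")
  expect_equal(nrow(out), 3L)
  expect_equal(out$hr[out$participant_id == "P1" &
                        out$date == as.Date("2024-01-01")], 65)  # last wins
  # identical duplicates are dropped silently
  d2 <- d[c(1, 1, 3), ]
  expect_silent(out2 <- deduplicate(d2))
  expect_equal(nrow(out2), 2L)
})

test_that("main-sleep filtering blanks sleep fields but keeps steps", {
  d <- data.frame(participant_id = "P1", date = as.Date("2024-01-01"),
                  hr = 60, temp_peak = 36.5, time_in_bed = 8, steps = 9000L,
                  is_main_sleep = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- filter_main_sleep(d)
  expect_equal(out$hr, c(60, NA))
  expect_equal(out$temp_peak, c(36.5, NA))
  expect_equal(out$time_in_bed, c(8, NA))
  expect_equal(out$steps, c(9000L, 9000L))
  expect_error(filter_main_sleep(d[, -7]), "is_main_sleep")
})

test_that("availability filter evaluates only reached windows", {
  lmp <- as.Date("2024-01-01")
  p <- rbind(
    make_profiles("A", lmp, end = lmp + 274),  # term: all four windows
    make_profiles("B", lmp, end = lmp + 70, outcome = "loss"),  # ends wk 10
    make_profiles("C", lmp, end = lmp + 274))
  mk_days <- function(id, days)
    data.frame(participant_id = id, date = lmp + days, hr = 60,
               stringsAsFactors = FALSE)
  d <- rbind(
    # A: dense everywhere except T2 at 39% (38 of 98 days)
    mk_days("A", c(-56:-1, 0:97, 98:135, 196:286)),
    # B: reaches only pre and a truncated T1 (denominator 71 days);
    #    30 of 71 T1 days ~ 42% and 24 of 56 pre days ~ 43%
    mk_days("B", c(seq(-56, -10, by = 2), seq(0, 58, by = 2))),
    # C: only 10 prepregnancy days ~ 18%
    mk_days("C", c(seq(-20, -11), 0:97, 98:195, 196:286)))
  suppressWarnings(a <- align_to_pregnancy(d, p))
  res <- apply_availability_filter(a, p, threshold = 0.40)
  expect_equal(res$profiles$participant_id, "B")
  expect_setequal(res$exclusions$participant_id, c("A", "C"))
  expect_equal(res$exclusions$window[res$exclusions$participant_id == "A"], "T2")
  expect_equal(res$exclusions$window[res$exclusions$participant_id == "C"], "pre")
  ecov <- res$exclusions$coverage[res$exclusions$participant_id == "A"]
  expect_equal(ecov, 38 / 98, tolerance = 1e-12)
})

test_that("baseline statistics over days -28..-1 with validity rules", {
  lmp <- as.Date("2024-03-01")
  p <- make_profiles("P1", lmp, end = lmp + 274)
  d <- data.frame(participant_id = "P1", date = lmp + c(-40, -3, -2, -1),
                  hr = c(999, 1, 2, 3), stringsAsFactors = FALSE)
  a <- align_to_pregnancy(d, p)
  bl <- compute_baseline(a, "hr", min_days = 3L)
  expect_equal(bl$mean, 2)      # day -40 is outside the baseline window
  expect_equal(bl$sd, 1)
  expect_equal(bl$n_days, 3L)
  expect_true(bl$valid)
  expect_false(compute_baseline(a, "hr", min_days = 7L)$valid)
  # constant series: sd below the floor invalidates the baseline
  d$hr <- 60
  bl2 <- compute_baseline(align_to_pregnancy(d, p), "hr", min_days = 3L)
  expect_false(bl2$valid)
})

test_that("weekly aggregation bins days 7w..7w+6 without imputation", {
  lmp <- as.Date("2024-03-01")
  p <- make_profiles("P1", lmp, end = lmp + 274)
  d <- data.frame(participant_id = "P1",
                  date = lmp + c(0, 6, 7, 21), hr = c(60, 64, 70, 80),
                  stringsAsFactors = FALSE)
  wk <- weekly_aggregate(align_to_pregnancy(d, p), "hr")
  expect_equal(wk$gestational_week, c(0, 1, 3))   # week 2 absent, not imputed
  expect_equal(wk$value_raw, c(62, 70, 80))
})

test_that("z-scoring divides out the individual baseline", {
  weekly <- data.frame(participant_id = "P1", metric = "hr",
                       gestational_week = 0:1, value_raw = c(64, 70))
  bl <- data.frame(participant_id = "P1", metric = "hr", mean = 60, sd = 2,
                   n_days = 28L, valid = TRUE)
  z <- zscore_weekly(weekly, bl)
  expect_equal(z$value_z, c(2, 5))
  # invalid baselines drop the participant-metric series
  bl$valid <- FALSE
  expect_equal(nrow(zscore_weekly(weekly, bl)), 0L)
})

test_that("interpolation fills short interior gaps only", {
  g <- interpolate_daily(c(1, 2, 5, 6), c(10, 20, 50, 60))
  expect_equal(g$day, 1:6)
  expect_equal(g$value, c(10, 20, 30, 40, 50, 60))  # linear interior fill
  # a gap longer than max_gap stays missing
  g2 <- interpolate_daily(c(1, 10), c(0, 90), max_gap = 7L)
  expect_equal(g2$value, c(0, rep(NA_real_, 8), 90))
  g3 <- interpolate_daily(c(1, 10), c(0, 90), max_gap = 8L)
  expect_equal(g3$value, seq(0, 90, by = 10))
  # leading and trailing missingness is never filled
  g4 <- interpolate_daily(1:5, c(NA, 2, NA, 4, NA))
  expect_equal(g4$value, c(NA, 2, 3, 4, NA))
})

test_that("interpolation commutes with day shifts and preserves monotonicity", {
  day <- c(3, 4, 8, 11, 12)
  val <- c(1, 2, 5, 9, 11)
  a <- interpolate_daily(day, val)
  b <- interpolate_daily(day + 100, val)
  expect_equal(a$value, b$value)
  expect_equal(b$day, a$day + 100)
  expect_false(is.unsorted(a$value))
})

test_that("daily z-scores are centered on the participant's own baseline", {
  ch <- small_cohort(n = 6L, seed = 31L, missing_day_rate = 0, nap_rate = 0)
  pw <- prepare_weekly(ch$daily, ch$profiles, metrics = "hr")
  zs <- daily_zscores(pw$daily, pw$baselines, "hr")
  one <- zs[zs$participant_id == zs$participant_id[1] &
              zs$day_offset >= -28 & zs$day_offset <= -1, ]
  expect_equal(mean(one$value_z), 0, tolerance = 1e-10)
  expect_equal(sd(one$value_z), 1, tolerance = 1e-10)
})

test_that("prepare_weekly chains the steps consistently", {
  ch <- small_cohort(n = 12L, seed = 32L)
  pw <- prepare_weekly(ch$daily, ch$profiles, metrics = c("hr", "steps"))
  expect_named(pw, c("weekly_z", "baselines", "daily", "profiles", "exclusions"))
  expect_true(all(pw$weekly_z$participant_id %in% pw$profiles$participant_id))
  expect_setequal(unique(pw$weekly_z$metric), c("hr", "steps"))
  expect_true(all(pw$weekly_z$gestational_week >= -8))
  # z-scores recompute from the returned baselines
  m <- merge(pw$weekly_z,
             pw$baselines[pw$baselines$metric == "hr", ],
             by = c("participant_id", "metric"))
  expect_equal(m$value_z, (m$value_raw - m$mean) / m$sd, tolerance = 1e-12)
})
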