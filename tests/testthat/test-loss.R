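# build a z series data frame on a day grid
zser <- function(id, days, z) {
  data.frame(participant_id = id, day_offset = days, value_z = z,
             stringsAsFactors = FALSE)
}

test_that("window extraction: end at 7w1d spans 3w2d to 7w1d, 28 days", {
  s <- zser("P1", -56:120, as.numeric(-56:120))
  w <- extract_window(s, end_day = 50L)   # 7 weeks 1 day
  expect_equal(nrow(w), 28L)
  expect_equal(w$day_rel, -27:0)
  expect_equal(w$value_z, 23:50)          # gestational days 23..50 = 3w2d..7w1d
  # ends before day 28 cannot host a full within-pregnancy window
  expect_null(extract_window(s, 27L))
  w28 <- extract_window(s, 28L)
  expect_equal(w28$value_z, 1:28)
  # days absent from the series come back missing
  w2 <- extract_window(zser("P1", 40:50, 1), 50L)
  expect_equal(sum(is.na(w2$value_z)), 17L)
})

test_that("control matching is seeded, without reuse, and coverage-checked", {
  cases <- data.frame(participant_id = sprintf("L%02d", 1:30),
                      end_day = rep(60L, 30))
  obs_days <- setNames(rep(list(1:100), 40), sprintf("T%02d", 1:40))
  p1 <- sample_controls(cases, obs_days, seed = 7L)
  p2 <- sample_controls(cases, obs_days, seed = 7L)
  expect_identical(p1, p2)
  expect_false(any(duplicated(p1$control_id)))  # pool not exhausted: no reuse
  expect_true(all(p1$control_coverage == 1))
  expect_equal(p1$window_start, p1$end_day - 27L)
  p3 <- sample_controls(cases, obs_days, seed = 8L)
  expect_false(identical(p1$control_id, p3$control_id))
  # a pool with no coverage in the window errors
  bad <- setNames(rep(list(200:210), 40), names(obs_days))
  expect_error(sample_controls(cases, bad, seed = 1L), "exhausted")
  # once the pool is used up, controls are reused rather than failing
  few <- obs_days[1:5]
  p4 <- sample_controls(cases, few, seed = 1L)
  expect_equal(nrow(p4), 30L)
  expect_true(any(duplicated(p4$control_id)))
})

test_that("effect sizes and onset follow from the fitted curves exactly", {
  curves <- data.frame(day_rel = -27:0, term = 0,
                       loss = ifelse(-27:0 >= -13, -0.3, 0))
  res <- structure(list(curves = curves), class = "loss_divergence")
  es <- effect_sizes(res)
  expect_equal(es[["delta_28d"]], 0.3 * 14 / 28)
  expect_equal(es[["delta_7d"]], 0.3)
  expect_equal(estimate_divergence_onset(res, q = 0.25), -13L)
  # a divergence not sustained through day 0 yields NA
  curves$loss <- ifelse(-27:0 >= -20 & -27:0 <= -5, -0.4, 0)
  expect_true(is.na(estimate_divergence_onset(
    structure(list(curves = curves), class = "loss_divergence"))))
  # threshold q is respected
  curves$loss <- -0.2
  expect_true(is.na(estimate_divergence_onset(
    structure(list(curves = curves), class = "loss_divergence"), q = 0.25)))
  expect_equal(estimate_divergence_onset(
    structure(list(curves = curves), class = "loss_divergence"), q = 0.1), -27L)
})

test_that("divergence model recovers a unit hinge with light noise", {
  set.seed(51)
  n_pairs <- 20L
  ids_l <- sprintf("L%02d", 1:n_pairs)
  ids_t <- sprintf("T%02d", 1:n_pairs)
  ends <- sample(40:90, n_pairs, TRUE)
  hinge <- function(day_rel) ifelse(day_rel > -14, -(day_rel + 14) / 14, 0)
  zs <- rbind(
    do.call(rbind, Map(function(id, e)
      zser(id, (e - 27):e, hinge((e - 27):e - e) + rnorm(28, 0, 0.05)),
      ids_l, ends)),
    do.call(rbind, Map(function(id, e)
      zser(id, (e - 27):e, rnorm(28, 0, 0.05)), ids_t, ends)))
  pairs <- data.frame(case_id = ids_l, control_id = ids_t, end_day = ends,
                      window_start = ends - 27L, control_coverage = 1)
  fit <- fit_loss_model(pairs, zs, metric = "tib")
  expect_s3_class(fit, "loss_divergence")
  expect_lt(fit$outcome_wald$p.value, 1e-6)
  expect_equal(fit$outcome_wald$df, 2L)
  # the linear-in-day outcome contrast summarizes the hinge: its least-squares
  # projection crosses -0.25 z near day -14, so the onset lands close to truth
  expect_true(fit$onset_day %in% -16:-12)
  # final-7-day mean deficit ~ 0.68 z; 28-day mean ~ 0.27 z (hinge projection)
  expect_gt(fit$delta_7d, 0.55)
  expect_lt(fit$delta_7d, 0.85)
  expect_gt(fit$delta_28d, 0.15)
  expect_lt(fit$delta_28d, 0.40)
  expect_output(print(fit), "matched pairs")
})

test_that("deltas and onset are invariant to a common curve", {
  set.seed(52)
  n_pairs <- 15L
  ids_l <- sprintf("L%02d", 1:n_pairs)
  ids_t <- sprintf("T%02d", 1:n_pairs)
  ends <- rep(60L, n_pairs)
  hinge <- function(day_rel) ifelse(day_rel > -14, -(day_rel + 14) / 14, 0)
  noise <- function() rnorm(28, 0, 0.05)
  mk <- function(common) {
    zs <- rbind(
      do.call(rbind, Map(function(id, e) {
        dr <- (e - 27):e - e
        zser(id, (e - 27):e, hinge(dr) + common(dr) + noise())
      }, ids_l, ends)),
      do.call(rbind, Map(function(id, e) {
        dr <- (e - 27):e - e
        zser(id, (e - 27):e, common(dr) + noise())
      }, ids_t, ends)))
    pairs <- data.frame(case_id = ids_l, control_id = ids_t, end_day = ends,
                        window_start = ends - 27L, control_coverage = 1)
    fit_loss_model(pairs, zs)
  }
  set.seed(53); f0 <- mk(function(dr) 0)
  set.seed(53); f1 <- mk(function(dr) 0.5 * sin(dr / 5))
  expect_equal(f0$delta_28d, f1$delta_28d, tolerance = 1e-6)
  expect_equal(f0$delta_7d, f1$delta_7d, tolerance = 1e-6)
  expect_equal(f0$onset_day, f1$onset_day)
})

test_that("outcome Wald p-values are uniform when groups are exchangeable", {
  set.seed(54)
  n_pairs <- 25L
  ends <- rep(60L, n_pairs)
  ids_l <- sprintf("L%02d", 1:n_pairs)
  ids_t <- sprintf("T%02d", 1:n_pairs)
  pairs <- data.frame(case_id = ids_l, control_id = ids_t, end_day = ends,
                      window_start = ends - 27L, control_coverage = 1)
  pvals <- replicate(200, {
    zs <- do.call(rbind, Map(function(id, e)
      zser(id, (e - 27):e, rnorm(1, 0, 0.5) + rnorm(28)),
      c(ids_l, ids_t), rep(ends, 2)))
    fit_loss_model(pairs, zs)$outcome_wald$p.value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("end-to-end loss analysis runs on a raw cohort deterministically", {
  ch <- small_cohort(n = 90L, seed = 55L,
                     proportions = c(term = 0.5, preterm = 0, loss = 0.5))
  r1 <- loss_divergence_analysis(ch$daily, ch$profiles, "time_in_bed",
                                 seed = 9L, n_pairs = 20L)
  r2 <- loss_divergence_analysis(ch$daily, ch$profiles, "time_in_bed",
                                 seed = 9L, n_pairs = 20L)
  expect_equal(r1$n_pairs, 20L)
  expect_identical(r1$pairs, r2$pairs)
  expect_equal(r1$delta_28d, r2$delta_28d)
  expect_lt(r1$outcome_wald$p.value, 0.05)
  expect_error(loss_divergence_analysis(ch$daily, ch$profiles, "time_in_bed",
                                        seed = 9L, n_pairs = 5L),
               "fewer than 10")
})
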