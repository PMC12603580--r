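# Trajectory templates: the generator's ground-truth mean curves. Each
# template is a piecewise-linear deviation (native units) from the
# individual prepregnancy baseline as a function of gestational week, with
# optional linear age/BMI modifiers, plus the pre-loss divergence the loss
# analysis is meant to detect.

#' Construct a trajectory template
#'
#' A template stores the population mean deviation of one metric from its
#' prepregnancy baseline, in native units, as piecewise-linear anchors over
#' gestational weeks. Modifier slopes tilt the deviation linearly in age and
#' BMI around the cohort reference values (age 32.2 y, BMI 25.3 kg/m^2);
#' modifiers act only during gestation and postpartum (week >= 0) so the
#' prepregnancy baseline stays identifiable. `loss_end_deviation` is the
#' additional native-unit deviation reached on the final day of a pregnancy
#' ending in loss, ramped in linearly over the divergence-onset window.
#'
#' @param metric metric name (a `daily.csv` column).
#' @param anchors 2-column matrix/data frame: gestational week (strictly
#'   increasing, first one prepregnancy) and mean deviation (0 at the first
#'   anchor).
#' @param age_modifier deviation slope per year of age (native units).
#' @param bmi_modifier deviation slope per kg/m^2 of BMI (native units).
#' @param loss_end_deviation native-unit deviation at the day of pregnancy
#'   loss, relative to the term template.
#' @return object of class `trajectory_template`.
#' @export
trajectory_template <- function(metric, anchors, age_modifier = 0,
                                bmi_modifier = 0, loss_end_deviation = 0) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2L, nrow(anchors) >= 2L)
  colnames(anchors) <- c("week", "deviation")
  if (any(diff(anchors[, "week"]) <= 0))
    stop("anchor weeks must be strictly increasing")
  if (anchors[1L, "week"] > 0)
    stop("the first anchor must lie at or before week 0 (prepregnancy)")
  if (abs(anchors[1L, "deviation"]) > 1e-12)
    stop("deviation at the first (prepregnancy) anchor must be 0")
  structure(list(metric = metric, anchors = anchors,
                 age_modifier = age_modifier, bmi_modifier = bmi_modifier,
                 loss_end_deviation = loss_end_deviation),
            class = "trajectory_template")
}

#' @export
print.trajectory_template <- function(x, ...) {
  cat("Trajectory template for", x$metric, "\n")
  print(x$anchors)
  if (x$age_modifier != 0 || x$bmi_modifier != 0)
    cat(sprintf("modifiers: %.4g / year of age, %.4g / kg/m^2\n",
                x$age_modifier, x$bmi_modifier))
  if (x$loss_end_deviation != 0)
    cat(sprintf("pre-loss end deviation: %.4g\n", x$loss_end_deviation))
  invisible(x)
}

#' Evaluate a trajectory template
#'
#' Piecewise-linear interpolation of the anchors plus
#' `age_modifier * (age - 32.2) + bmi_modifier * (bmi - 25.3)` for weeks
#' at or after pregnancy start.
#'
#' @param template a [trajectory_template()].
#' @param week gestational week(s); must lie within the anchor range.
#' @param age,bmi covariate values (defaults: the cohort reference values).
#' @return native-unit deviation(s) from baseline.
#' @export
evaluate_template <- function(template, week, age = .ref_age, bmi = .ref_bmi) {
  a <- template$anchors
  rng <- range(a[, "week"])
  if (any(week < rng[1L] - 1e-9 | week > rng[2L] + 1e-9))
    stop("week outside the template's anchor range [",
         rng[1L], ", ", rng[2L], "]")
  base <- stats::approx(a[, "week"], a[, "deviation"], xout = week,
                        rule = 2)$y
  shift <- (template$age_modifier * (age - .ref_age) +
              template$bmi_modifier * (bmi - .ref_bmi)) * as.numeric(week >= 0)
  base + shift
}

#' Default trajectory templates
#'
#' One template per generated metric, with anchors at the gestational-week
#' landmarks of term pregnancies: the first-trimester sleep peak at week 9
#' (time in bed +30 min = time asleep +15 min + time awake +15 min), nightly
#' wake rising past 3 baseline SDs around birth, the skin-temperature peak of
#' +0.3 degC at week 9 with a secondary +0.1 degC bump near week 41, the HR
#' first peak (+4.5 bpm, week 5), trough (week 9) and main peak (+10 bpm,
#' week 32) with HRV mirroring it (nadir below -15 ms), the respiratory-rate
#' peak (+1 breath/min, week 9), and the activity trough (about -2000 steps,
#' week 8) with the deepest deficit (beyond -2500 steps) near birth.
#' `time_in_bed` and `light_pct` are derived columns (sums/complements of the
#' generated components) whose templates are the corresponding sums.
#' Pre-loss end deviations are negative for time in bed, sleep, wake,
#' temperature, heart rate and respiratory rate, and zero for steps and HRV.
#'
#' @return named list of [trajectory_template()] objects.
#' @export
default_templates <- function() {
  # Landmarks are densified along a monotone-preserving smooth interpolant
  # (Fritsch-Carlson Hermite): physiological trajectories rise and fall
  # smoothly through their landmark values rather than in straight segments,
  # and the landmark values themselves (peaks, troughs) are hit exactly with
  # no overshoot between anchors.
  mk <- function(metric, ..., age_modifier = 0, bmi_modifier = 0,
                 loss_end_deviation = 0) {
    pts <- matrix(c(...), ncol = 2, byrow = TRUE)
    f <- stats::splinefun(pts[, 1], pts[, 2], method = "monoH.FC")
    wk <- sort(unique(c(seq(pts[1, 1], pts[nrow(pts), 1], by = 0.5), pts[, 1])))
    trajectory_template(metric, cbind(wk, f(wk)), age_modifier, bmi_modifier,
                        loss_end_deviation)
  }
  tl <- list(
    time_asleep = mk("time_asleep",
      -8, 0,  0, 0,  9, 0.25,  20, -0.05,  28, -0.15,
      38, -0.3,  40, -0.7,  42, -1.17,  50, -1.0,  56, -0.9,
      loss_end_deviation = -0.6),
    time_awake = mk("time_awake",
      -8, 0,  0, 0,  9, 0.25,  20, 0.17,  28, 0.2,  38, 0.35,
      40, 0.9,  42, 1.5,  50, 1.5,  56, 1.4,
      loss_end_deviation = -0.25),
    deep_pct = mk("deep_pct",
      -8, 0,  0, 0,  9, -1,  28, -2,  40, -3,  44, -1,  56, -0.5),
    rem_pct = mk("rem_pct",
      -8, 0,  0, 0,  9, -0.5,  28, -1.5,  40, -2.5,  44, -0.5,  56, 0),
    temp_peak = mk("temp_peak",
      -8, 0,  0, 0,  2, 0.05,  4, 0.2,  9, 0.3,  14, 0.15,  20, 0.02,
      28, -0.08,  32, -0.1,  36, -0.12,  39, -0.1,  41, -0.02,
      44, -0.12,  56, -0.15,
      loss_end_deviation = -0.3),
    hr = mk("hr",
      -8, 0,  0, 0,  5, 4.5,  9, 2.5,  21, 7,  32, 10,  38, 9.5,
      40, 6,  42, 0,  46, -0.5,  56, 0,
      loss_end_deviation = -3),
    hrv = mk("hrv",
      -8, 0,  0, 0,  5, -11,  9, -6,  21, -12,  32, -16.5,  38, -15,
      40, -8,  42, -1,  46, 0,  56, 0),
    rr = mk("rr",
      -8, 0,  0, 0,  5, 0.7,  9, 1,  14, 0.5,  18, 0.15,  24, 0,
      40, 0,  42, -0.5,  56, -0.3,
      loss_end_deviation = -0.8),
    steps = mk("steps",
      -8, 0,  0, 0,  8, -2000,  21, -1200,  40, -2800,  42, -2600,
      48, -1500,  56, -1000)
  )
  # derived-column templates: time in bed = asleep + awake;
  # light % = -(deep + rem) deviation around its baseline share
  sum_template <- function(metric, t1, t2, sign = 1) {
    wk <- sort(unique(c(t1$anchors[, "week"], t2$anchors[, "week"])))
    dev <- sign * (stats::approx(t1$anchors[, "week"], t1$anchors[, "deviation"],
                                 xout = wk)$y +
                   stats::approx(t2$anchors[, "week"], t2$anchors[, "deviation"],
                                 xout = wk)$y)
    trajectory_template(metric, cbind(wk, dev),
                        loss_end_deviation =
                          sign * (t1$loss_end_deviation + t2$loss_end_deviation))
  }
  tl$time_in_bed <- sum_template("time_in_bed", tl$time_asleep, tl$time_awake)
  tl$light_pct <- sum_template("light_pct", tl$deep_pct, tl$rem_pct, sign = -1)
  tl
}

# metrics actually drawn by the generator (others are derived)
.generated_metrics <- c("time_asleep", "time_awake", "deep_pct", "rem_pct",
                        "temp_peak", "hr", "hrv", "rr", "steps")
# all metric columns of daily.csv
.all_metrics <- c("time_in_bed", "time_asleep", "time_awake",
                  "light_pct", "deep_pct", "rem_pct",
                  "temp_peak", "hr", "hrv", "rr", "steps")
# metrics measured only during main nocturnal sleep
.sleep_metrics <- setdiff(.all_metrics, "steps")
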