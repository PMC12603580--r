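# Pregnancy timeline: start inference from self-reported dates, gestational
# age, trimester classification, and the 64-week analysis window
# (8 weeks prepregnancy + 56 weeks, day offsets -56..391, week = floor(day/7)).

#' Infer the pregnancy start date (first day of the last menstrual period)
#'
#' The expected due date, when recorded, takes precedence: start = due date
#' minus 280 days. Otherwise the self-reported LMP date is used directly.
#'
#' @param lmp_date,due_date `Date` vectors (either may contain `NA`, not both
#'   in the same position).
#' @return `Date` vector of pregnancy start dates.
#' @export
infer_pregnancy_start <- function(lmp_date, due_date) {
  lmp_date <- as.Date(lmp_date); due_date <- as.Date(due_date)
  if (any(is.na(lmp_date) & is.na(due_date)))
    stop("pregnancy start cannot be inferred: both LMP and due date missing")
  out <- due_date - 280L
  out[is.na(due_date)] <- lmp_date[is.na(due_date)]
  out
}

#' Summarize how pregnancy start dates were derived
#'
#' @param profiles profile data frame with `lmp_date` and `due_date` columns.
#' @return data frame with counts and percentages of due-date-derived and
#'   LMP-derived pregnancy starts.
#' @export
summarize_start_sources <- function(profiles) {
  n <- nrow(profiles)
  n_due <- sum(!is.na(profiles$due_date))
  data.frame(source = c("due_date", "lmp_date"),
             n = c(n_due, n - n_due),
             percent = round(100 * c(n_due, n - n_due) / n, 1))
}

#' Classify a gestational day offset into pregnancy phases
#'
#' Day 0 is the first day of the LMP. Trimester 1 covers 0w0d-13w6d
#' (days 0-97), trimester 2 14w0d-27w6d (days 98-195), trimester 3
#' 28w0d-40w6d (days 196-286); earlier days are prepregnancy and later days
#' postpartum.
#'
#' @param day_offset integer day offsets relative to pregnancy start.
#' @return factor with levels `pre`, `T1`, `T2`, `T3`, `post`.
#' @export
classify_trimester <- function(day_offset) {
  cut(day_offset, breaks = c(-Inf, -1, 97, 195, 286, Inf),
      labels = c("pre", "T1", "T2", "T3", "post"))
}

# half-open [start, end] day windows of each within-pregnancy phase
.trimester_windows <- list(pre = c(-56L, -1L), T1 = c(0L, 97L),
                           T2 = c(98L, 195L), T3 = c(196L, 286L))

#' Estimated conception date
#'
#' Conception is taken as 14 days after the pregnancy start (LMP day) in a
#' standard 28-day cycle.
#'
#' @param start `Date` vector of pregnancy start dates.
#' @return `Date` vector.
#' @export
estimated_conception <- function(start) as.Date(start) + 14L

#' Body mass index
#'
#' @param weight body weight in kg.
#' @param height height in m.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  weight / height^2
}

#' Align daily records to the pregnancy timeline
#'
#' Joins the inferred pregnancy start onto the daily records and adds
#' `day_offset` (days since pregnancy start), `gestational_week`
#' (`floor(day_offset / 7)`, so week w spans days 7w..7w+6) and `end_day`
#' (gestational day at pregnancy end). Records outside the 64-week analysis
#' window (day offsets -56..391) are dropped. Self-reported outcome labels
#' inconsistent with the gestational age at end are kept but flagged with a
#' warning (self-report noise is expected).
#'
#' @param daily daily record data frame.
#' @param profiles pregnancy profile data frame.
#' @return the daily data frame with timeline columns added.
#' @export
align_to_pregnancy <- function(daily, profiles) {
  start <- infer_pregnancy_start(profiles$lmp_date, profiles$due_date)
  idx <- match(daily$participant_id, profiles$participant_id)
  if (anyNA(idx)) stop("daily records for participants absent from profiles")
  out <- daily
  out$day_offset <- as.integer(daily$date - start[idx])
  out$gestational_week <- floor(out$day_offset / 7)
  end_day <- as.integer(profiles$end_date - start)
  out$end_day <- end_day[idx]
  out$outcome <- profiles$outcome[idx]
  bad <- (profiles$outcome == "loss" & !(end_day >= 28 & end_day < 140)) |
    (profiles$outcome == "preterm" & !(end_day >= 140 & end_day < 259)) |
    (profiles$outcome == "term" & !(end_day >= 259 & end_day <= 294))
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " pregnancies have outcome labels inconsistent with their ",
            "gestational age at end (kept; self-report noise)")
  out[out$day_offset >= -56L & out$day_offset <= 391L, , drop = FALSE]
}
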