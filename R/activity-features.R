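#' Sufficient activity indicator
#'
#' Daily step counts above 7000 (strictly) count as sufficient activity.
#'
#' @param step_counts daily step total (vectorised).
#' @return logical; `NA` where missing.
#' @export
sufficient_activity <- function(step_counts) {
  ifelse(is.na(step_counts), NA, step_counts > 7000)
}

#' Ten summary statistics of an hourly distribution
#'
#' Mean, minimum, median, maximum, SD (sample), IQR, range, skewness,
#' kurtosis and root mean square of the included hourly bins. Skewness
#' and kurtosis use population moments (no bias correction) and kurtosis
#' is *excess* kurtosis (normal gives 0); both are defined as 0 for a
#' zero-variance series.
#'
#' @param values numeric vector of included hourly bins.
#' @param prefix name prefix for the returned statistics.
#' @return named numeric vector of length 10; all `NA` with fewer than
#'   two bins.
#' @export
distribution_stats <- function(values, prefix = "") {
  nm <- paste0(prefix, c("mean", "min", "median", "max", "sd", "iqr",
                         "range", "skewness", "kurtosis", "rms"))
  values <- values[!is.na(values)]
  if (length(values) < 2) return(stats::setNames(rep(NA_real_, 10), nm))
  m <- mean(values)
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 - 3 else 0
  stats::setNames(
    c(m, min(values), stats::median(values), max(values), stats::sd(values),
      stats::IQR(values), diff(range(values)), skew, kurt,
      sqrt(mean(values^2))), nm)
}

#' Hourly step and activity-duration series for one day
#'
#' Ten-minute records are summed into clock-aligned local-time hourly
#' bins. A bin counts as worn when at least `min_worn_min` minutes of
#' records fall in it; unworn bins are excluded (`NA`) rather than
#' counted as zero, so an unworn afternoon does not masquerade as
#' sedentary time.
#'
#' @param records data.frame of 10-minute activity records with columns
#'   `interval_start` (POSIXct), `steps`, `active_min`.
#' @param day Date of the day to bin.
#' @param min_worn_min minimum worn minutes for a bin to be included.
#' @return list with numeric vectors `steps` and `duration` of length 24
#'   (hours 0-23; `NA` = excluded bin) and `worn_min` per hour.
#' @export
hourly_series <- function(records, day, min_worn_min = 30) {
  day <- as.Date(day)
  steps <- duration <- rep(NA_real_, 24)
  worn <- rep(0, 24)
  if (!is.null(records) && nrow(records)) {
    rec_day <- as.Date(records$interval_start, tz = "UTC")
    records <- records[rec_day == day, , drop = FALSE]
    if (nrow(records)) {
      hr <- as.integer(format(records$interval_start, "%H", tz = "UTC"))
      for (h in unique(hr)) {
        sel <- hr == h
        worn[h + 1] <- 10 * sum(sel)
        steps[h + 1] <- sum(records$steps[sel])
        duration[h + 1] <- sum(records$active_min[sel])
      }
    }
  }
  excl <- worn < min_worn_min
  steps[excl] <- NA
  duration[excl] <- NA
  list(steps = steps, duration = duration, worn_min = worn)
}

#' Daily physical-activity feature row
#'
#' Aggregates a day's 10-minute records over the participant's awake
#' time: totals of steps, walking and running steps, distance, activity
#' duration and intensity; sedentary time (awake minutes without walking
#' or running activity); the sufficient-activity indicator; and the ten
#' distribution statistics of hourly step counts and hourly activity
#' duration (awake, worn hours only by default).
#'
#' @param records data.frame of 10-minute records (columns
#'   `interval_start`, `steps`, `walking_steps`, `running_steps`,
#'   `distance_m`, `active_min`, `intensity`).
#' @param day Date.
#' @param awake_start,awake_end POSIXct bounds of awake time.
#' @param hourly_all_hours include all worn hours (not just awake ones)
#'   in the distribution statistics.
#' @return named numeric vector of the 28 activity features, or
#'   all-missing when no awake-time records exist.
#' @export
aggregate_daily <- function(records, day, awake_start, awake_end,
                            hourly_all_hours = FALSE) {
  nm <- c("step_counts", "walking_steps", "running_steps", "distance_m",
          "activity_duration_min", "activity_intensity", "sedentary_min",
          "sufficient_activity",
          paste0("hourly_steps_", c("mean", "min", "median", "max", "sd",
                                    "iqr", "range", "skewness", "kurtosis",
                                    "rms")),
          paste0("hourly_duration_", c("mean", "min", "median", "max", "sd",
                                       "iqr", "range", "skewness", "kurtosis",
                                       "rms")))
  empty <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(records) || !nrow(records)) return(empty)
  day <- as.Date(day)
  rec_day <- as.Date(records$interval_start, tz = "UTC")
  records <- records[rec_day == day, , drop = FALSE]
  awake <- records[records$interval_start >= awake_start &
                     records$interval_start < awake_end, , drop = FALSE]
  if (!nrow(awake)) return(empty)

  awake_min <- as.numeric(difftime(awake_end, awake_start, units = "mins"))
  moving <- awake$walking_steps > 0 | awake$running_steps > 0
  totals <- c(step_counts = sum(awake$steps),
              walking_steps = sum(awake$walking_steps),
              running_steps = sum(awake$running_steps),
              distance_m = sum(awake$distance_m),
              activity_duration_min = sum(awake$active_min),
              activity_intensity = sum(awake$intensity),
              sedentary_min = awake_min - 10 * sum(moving),
              sufficient_activity =
                as.numeric(sufficient_activity(sum(awake$steps))))

  hb <- hourly_series(if (hourly_all_hours) records else awake, day)
  c(totals,
    distribution_stats(hb$steps, "hourly_steps_"),
    distribution_stats(hb$duration, "hourly_duration_"))
}
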