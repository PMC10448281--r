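#' Feature groups of the daily feature row
#'
#' @return named list of character vectors: `hrv` (7 resting HR/HRV
#'   parameters), `sleep` (6 nightly features), `pa` (28 daily activity
#'   features).
#' @export
feature_groups <- function() {
  stats10 <- c("mean", "min", "median", "max", "sd", "iqr", "range",
               "skewness", "kurtosis", "rms")
  list(
    hrv = c("hr", "avnn", "sdnn", "rmssd", "lf", "hf", "lf_hf"),
    sleep = c("tst", "fragmentation", "waso", "avg_hand_movement",
              "sleep_quality_indicator", "sufficient_sleep"),
    pa = c("step_counts", "walking_steps", "running_steps", "distance_m",
           "activity_duration_min", "activity_intensity", "sedentary_min",
           "sufficient_activity", paste0("hourly_steps_", stats10),
           paste0("hourly_duration_", stats10)))
}

# window-level HRV records for one bundle: data.frame(start_time, hr, ...)
bundle_hrv_windows <- function(bundle, quality_model = NULL) {
  recs <- list()
  if (length(bundle$ibi_windows)) {
    recs <- lapply(bundle$ibi_windows, function(w) {
      ib <- clean_ibis(intervals = w$intervals, window_duration_s = 300)
      c(start = as.numeric(w$start_time), hrv_record(ib))
    })
  } else if (length(bundle$ppg_segments)) {
    for (seg in bundle$ppg_segments) {
      res <- process_segment(seg, quality_model)
      for (r in res) {
        if (is.null(r$ibis)) next
        recs[[length(recs) + 1]] <- c(start = as.numeric(r$window$start_time),
                                      hrv_record(r$ibis))
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(start_time = as.POSIXct(character(0), tz = "UTC")))
  }
  m <- do.call(rbind, recs)
  out <- as.data.frame(m[, -1, drop = FALSE])
  out$start_time <- as.POSIXct(m[, "start"], origin = "1970-01-01", tz = "UTC")
  out
}

#' Extract the daily feature table and day summaries from one bundle
#'
#' Runs the three feature stages over a participant bundle: resting
#' HR/HRV per night (lowest-HR reliable sleep window, attributed to the
#' day the sleep period ends), nightly sleep features, and daily
#' activity features over the awake interval (morning sleep offset to
#' evening sleep onset). Also derives the day summaries that feed the
#' valid-day rule: awake wear minutes (10 per recorded activity
#' interval) and presence of valid sleep.
#'
#' @param bundle a `participant_bundle` (or equivalent list read from
#'   CSV with the same element names).
#' @param quality_model optional PPG quality model; only used on raw
#'   waveform data.
#' @return list with data.frames `daily` (participant_id, date, 41
#'   feature columns) and `summary` (participant_id, date,
#'   wear_min_awake, has_valid_sleep, valid).
#' @export
extract_daily_features <- function(bundle, quality_model = NULL) {
  groups <- feature_groups()
  feat_names <- unlist(groups, use.names = FALSE)
  sleep <- bundle$sleep_nights
  act <- bundle$activity_records
  hrvw <- bundle_hrv_windows(bundle, quality_model)

  days <- sort(unique(c(
    if (nrow(sleep)) sleep$date,
    if (!is.null(act) && nrow(act)) as.Date(act$interval_start, tz = "UTC"))))
  if (!length(days)) {
    empty <- data.frame(participant_id = character(0))
    return(list(daily = empty, summary = empty))
  }

  daily <- data.frame()
  summary <- data.frame()
  for (day in as.list(days)) {
    night <- sleep[sleep$date == day, , drop = FALSE]
    night <- if (nrow(night)) night[1, , drop = FALSE] else NULL
    has_sleep <- !is.null(night) && sleep_night_valid(night)

    sleep_row <- derive_sleep_row(if (has_sleep) night else NULL)

    # resting HRV: lowest-HR window within the night's sleep interval
    hrv_row <- stats::setNames(rep(NA_real_, 7), groups$hrv)
    if (has_sleep && nrow(hrvw)) {
      rest <- select_resting(hrvw, night$sleep_onset, night$sleep_offset)
      if (!is.null(rest)) hrv_row[] <- unlist(rest[1, groups$hrv])
    }

    # awake interval: this morning's sleep offset to tonight's onset
    awake_start <- if (has_sleep) night$sleep_offset else
      as.POSIXct(paste(day, "07:00:00"), tz = "UTC")
    next_night <- sleep[sleep$date == day + 1, , drop = FALSE]
    awake_end <- if (nrow(next_night)) next_night$sleep_onset[1] else
      as.POSIXct(paste(day, "23:00:00"), tz = "UTC")
    act_row <- aggregate_daily(act, day, awake_start, awake_end)

    wear <- 0
    if (!is.null(act) && nrow(act)) {
      wear <- 10 * sum(act$interval_start >= awake_start &
                         act$interval_start < awake_end &
                         as.Date(act$interval_start, tz = "UTC") == day)
    }

    row <- c(hrv_row, sleep_row, act_row)[feat_names]
    daily <- rbind(daily, cbind(
      data.frame(participant_id = bundle$participant_id, date = day),
      as.data.frame(as.list(row))))
    summary <- rbind(summary, data.frame(
      participant_id = bundle$participant_id, date = day,
      wear_min_awake = wear, has_valid_sleep = has_sleep,
      valid = is_valid_day(wear, has_sleep)))
  }
  rownames(daily) <- rownames(summary) <- NULL
  list(daily = daily, summary = summary)
}

#' Extract features for a whole cohort
#'
#' @param cohort list of participant bundles from [generate_cohort()].
#' @param quality_model optional PPG quality model.
#' @return list of stacked `daily` and `summary` data.frames plus the
#'   pooled `ucla` responses.
#' @export
extract_cohort_features <- function(cohort, quality_model = NULL) {
  parts <- lapply(cohort, extract_daily_features, quality_model = quality_model)
  list(daily = do.call(rbind, lapply(parts, `[[`, "daily")),
       summary = do.call(rbind, lapply(parts, `[[`, "summary")),
       ucla = do.call(rbind, lapply(cohort, `[[`, "ucla_responses")))
}
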