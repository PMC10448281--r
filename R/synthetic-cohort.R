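# Synthetic wearable cohort with known ground truth. The generator plants
# the class effects the pipeline is supposed to recover (lower activity
# intensity, flatter intra-day step distribution, lower resting SDNN in the
# lonely class) and otherwise draws from simple distributions chosen to be
# realistic for free-living adults; the vignette documents every choice.

#' Configuration of a synthetic cohort
#'
#' @param n_participants number of participants (>= 2).
#' @param loneliness_prevalence fraction of participants in the lonely
#'   class; exactly `round(n * prevalence)` participants carry label 1.
#' @param effect_multipliers planted class effects for the lonely group:
#'   `activity_intensity` scales daily activity intensity,
#'   `resting_sdnn` scales resting SDNN, `step_kurtosis_shift` in `[0, 1]`
#'   blends the hourly step profile toward uniform (flattening the
#'   distribution, shifting its kurtosis toward 0).
#' @param missing_day_rate probability that any given day's data (all
#'   streams) is dropped.
#' @param ppg_noise_sd additive white-noise SD on the PPG waveform, in
#'   units of the unit-amplitude pulse template.
#' @param fast_mode emit interbeat-interval series directly (skipping
#'   waveform synthesis and peak detection); sleep-period windows only.
#' @param seed integer seed; identical configs produce identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 40L, loneliness_prevalence = 0.4,
                          effect_multipliers = list(), missing_day_rate = 0.15,
                          ppg_noise_sd = 0.05, fast_mode = FALSE, seed = 1L) {
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (loneliness_prevalence < 0 || loneliness_prevalence > 1)
    stop("loneliness_prevalence must lie in [0, 1]")
  if (missing_day_rate < 0 || missing_day_rate > 1)
    stop("missing_day_rate must lie in [0, 1]")
  if (ppg_noise_sd < 0) stop("ppg_noise_sd must be nonnegative")
  em <- list(activity_intensity = 0.6, step_kurtosis_shift = 0.5,
             resting_sdnn = 0.8)
  bad <- setdiff(names(effect_multipliers), names(em))
  if (length(bad)) stop("unknown effect multipliers: ", paste(bad, collapse = ", "))
  em[names(effect_multipliers)] <- effect_multipliers
  structure(list(n_participants = as.integer(n_participants),
                 loneliness_prevalence = loneliness_prevalence,
                 effect_multipliers = em,
                 missing_day_rate = missing_day_rate,
                 ppg_noise_sd = ppg_noise_sd,
                 fast_mode = isTRUE(fast_mode),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  force(code)
}

# questionnaire dates emulating gestational week 36 and postpartum week 12
.tp_dates <- function() as.Date(c("2023-03-08", "2023-06-08"))

#' Generate a synthetic interbeat-interval series
#'
#' Intervals are a constant mean (60000 / HR) plus a sinusoidal
#' modulation at `modulation_hz` and white noise; modulation and noise
#' split the target variance 60/40, so the series has SD close to
#' `sdnn_target_ms` with a clear spectral line at the modulation
#' frequency.
#'
#' @param mean_hr_bpm mean heart rate, 30-220 bpm.
#' @param sdnn_target_ms target interval SD in ms (0 gives identical
#'   intervals); must be below the mean interval.
#' @param modulation_hz frequency of the sinusoidal modulation, Hz.
#' @param duration_s series duration; intervals are emitted until their
#'   sum reaches `duration_s * 1000` ms.
#' @param seed integer seed.
#' @return numeric vector of intervals in ms.
#' @export
generate_ibi_series <- function(mean_hr_bpm, sdnn_target_ms = 0,
                                modulation_hz = 0.25, duration_s = 300,
                                seed = 1L) {
  if (mean_hr_bpm < 30 || mean_hr_bpm > 220) stop("mean_hr_bpm out of range")
  if (duration_s <= 0) stop("duration_s must be positive")
  m <- 60000 / mean_hr_bpm
  if (sdnn_target_ms >= m) stop("sdnn_target_ms exceeds the mean interval")
  with_seed(seed, {
    n <- ceiling(duration_s * 1000 / m) + 8L
    t_nom <- (seq_len(n) - 1) * m / 1000
    x <- rep(m, n)
    if (sdnn_target_ms > 0) {
      amp <- sqrt(2 * 0.6) * sdnn_target_ms
      x <- x + amp * sin(2 * pi * modulation_hz * t_nom) +
        rnorm(n, 0, sqrt(0.4) * sdnn_target_ms)
      x <- pmin(pmax(x, 300), 2000)
    }
    cs <- cumsum(x)
    k <- which(cs >= duration_s * 1000)[1]
    if (is.na(k)) k <- n
    x[seq_len(k)]
  })
}

# pulse template on phase [0, 1): systolic peak at 0.25, small dicrotic
# bump at 0.65 (amplitudes chosen so the band-limited waveform keeps its
# maximum within a fraction of a sample of the systolic peak)
.pulse_template <- function(phase) {
  exp(-((phase - 0.25) / 0.09)^2) + 0.2 * exp(-((phase - 0.65) / 0.08)^2)
}

#' Synthesise a PPG waveform from an interval series
#'
#' Each cardiac cycle is a fixed two-Gaussian template (systolic peak +
#' dicrotic bump) resampled to the cycle's interval; the stored true
#' peak times are the systolic maxima.
#'
#' @param ibi_series intervals in ms.
#' @param fs_hz sampling frequency (must be at least 7 Hz, twice the
#'   3.5 Hz upper cardiac band).
#' @param noise_sd additive white-noise SD (template has unit amplitude).
#' @param seed integer seed (noise only).
#' @param participant_id,start_time segment metadata.
#' @return a [ppg_segment()] with attribute `true_peak_times_s` (seconds
#'   from segment start).
#' @export
generate_ppg <- function(ibi_series, fs_hz = 20, noise_sd = 0, seed = 1L,
                         participant_id = "sim",
                         start_time = as.POSIXct("2023-01-01", tz = "UTC")) {
  if (length(ibi_series) == 0) stop("empty ibi_series")
  if (fs_hz < 7) stop("fs_hz undersamples the cardiac band (need >= 7 Hz)")
  starts_s <- c(0, cumsum(ibi_series / 1000))
  dur <- starts_s[length(starts_s)]
  n <- round(dur * fs_hz)
  tt <- (seq_len(n) - 1) / fs_hz
  cyc <- findInterval(tt, starts_s, rightmost.closed = FALSE)
  cyc <- pmin(pmax(cyc, 1L), length(ibi_series))
  phase <- (tt - starts_s[cyc]) / (ibi_series[cyc] / 1000)
  x <- .pulse_template(pmin(pmax(phase, 0), 1))
  if (noise_sd > 0) x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  seg <- ppg_segment(participant_id, start_time, fs_hz, x)
  attr(seg, "true_peak_times_s") <- starts_s[-length(starts_s)] +
    0.25 * ibi_series / 1000
  seg
}

# ---- participant-level generation -----------------------------------------

ucla_items_for_score <- function(score) {
  it <- rep(1L, 6)
  rem <- score - 6L
  while (rem > 0L) {
    cand <- which(it < 4L)
    i <- cand[sample.int(length(cand), 1L)]
    it[i] <- it[i] + 1L
    rem <- rem - 1L
  }
  it
}

generate_participant <- function(id, label, config) {
  em <- config$effect_multipliers
  tp <- .tp_dates()
  days <- sort(unique(c(seq(tp[1] - 7, tp[1], by = "day"),
                        seq(tp[2] - 7, tp[2], by = "day"))))

  hr_awake <- rnorm(1, 75, 6)
  hr_sleep <- hr_awake - runif(1, 8, 14)
  sdnn_rest <- min(max(rnorm(1, 55, 10), 25), 95)
  if (label == 1) sdnn_rest <- sdnn_rest * em$resting_sdnn
  resp_hz <- runif(1, 0.2, 0.3)
  int_base <- rlnorm(1, log(5), 0.1)
  steps_base <- rlnorm(1, log(9000), 0.2)

  sleep <- data.frame()
  activity <- data.frame()
  ibi_windows <- list()
  ppg_segments <- list()
  gt_day <- data.frame()

  for (d in seq_along(days)) {
    day <- days[d]
    # night ending on the morning of `day`
    onset <- as.POSIXct(paste(day - 1, "23:00:00"), tz = "UTC") +
      rnorm(1, 0, 20) * 60
    tst <- min(max(rnorm(1, 460, 35), 330), 560)
    waso <- min(rexp(1, 1 / 15), 120)
    offset <- onset + (tst + waso) * 60
    sleep <- rbind(sleep, data.frame(
      participant_id = id, date = day, sleep_onset = onset,
      sleep_offset = offset, tst_min = tst,
      fragmentation = rpois(1, 2), waso_min = waso,
      avg_hand_movement = rlnorm(1, log(0.3), 0.4), valid = TRUE))

    # awake interval: morning sleep offset to ~23:00 nominal onset
    awake_start <- offset
    awake_end <- as.POSIXct(paste(day, "23:00:00"), tz = "UTC")
    rec_start <- seq(ceil_10min(awake_start), awake_end - 1, by = 600)
    hr_of <- as.integer(format(rec_start, "%H", tz = "UTC"))
    # diurnal activity bump with day-to-day variation in its centre and
    # width; the lonely class gets a systematically flatter (wider) bump,
    # shifting the hourly step distribution's kurtosis toward 0
    sigma_h <- 3.5 * exp(rnorm(1, 0, 0.15))
    if (label == 1) sigma_h <- sigma_h * (1 + 0.6 * em$step_kurtosis_shift)
    w <- stats::dnorm(hr_of, rnorm(1, 13, 1.2), sigma_h)
    w <- w * exp(rnorm(length(w), 0, 0.4))
    # everyone has occasional near-sedentary hours (meetings, rest),
    # independent of class, so no hourly bin is a guaranteed floor
    hrs <- unique(hr_of)
    quiet <- stats::setNames(ifelse(runif(length(hrs)) < 0.2, 0.03, 1), hrs)
    w <- w * quiet[as.character(hr_of)]
    total <- steps_base * exp(rnorm(1, 0, 0.15))
    lambda <- total * w / sum(w)
    steps <- rpois(length(lambda), lambda)
    running <- rbinom(length(steps), steps, 0.03)
    walking <- round((steps - running) * runif(length(steps), 0.85, 0.95))
    intensity <- int_base * (steps / 1000)^1.1 * exp(rnorm(length(steps), 0, 0.15))
    if (label == 1) intensity <- intensity * em$activity_intensity
    activity <- rbind(activity, data.frame(
      participant_id = id, interval_start = rec_start, steps = steps,
      walking_steps = walking, running_steps = running,
      distance_m = round(0.7 * steps * runif(length(steps), 0.95, 1.05)),
      active_min = pmin(10, steps / 110), intensity = intensity))

    # PPG slots every other hour (12 per day), two 5-min windows each
    slot_times <- as.POSIXct(paste(day, sprintf("%02d:00:00", seq(0, 22, 2))),
                             tz = "UTC")
    day_ibi_means <- numeric(0)
    for (st in seq_along(slot_times)) {
      slot <- slot_times[st]
      in_sleep <- slot >= onset & slot <= offset
      if (config$fast_mode && !in_sleep) next
      hr_slot <- if (in_sleep) hr_sleep + rnorm(1, 0, 1.5) else
        hr_awake + rnorm(1, 0, 2.5)
      sdnn_slot <- sdnn_rest * exp(rnorm(1, 0, 0.1)) *
        if (in_sleep) 1 else 0.8
      if (config$fast_mode) {
        for (wk in 0:1) {
          iv <- generate_ibi_series(hr_slot, sdnn_slot, resp_hz, 300,
                                    seed = sample.int(2^31 - 1, 1))
          ibi_windows[[length(ibi_windows) + 1]] <- list(
            participant_id = id, date = day, start_time = slot + wk * 300,
            intervals = iv, true_mean_ms = 60000 / hr_slot,
            true_sdnn_ms = sdnn_slot)
          day_ibi_means <- c(day_ibi_means, mean(iv))
        }
      } else {
        iv <- generate_ibi_series(hr_slot, sdnn_slot, resp_hz, 720,
                                  seed = sample.int(2^31 - 1, 1))
        seg <- generate_ppg(iv, 20, config$ppg_noise_sd,
                            seed = sample.int(2^31 - 1, 1),
                            participant_id = id, start_time = slot)
        ppg_segments[[length(ppg_segments) + 1]] <- seg
        day_ibi_means <- c(day_ibi_means, mean(iv))
      }
    }
    gt_day <- rbind(gt_day, data.frame(
      participant_id = id, date = day,
      true_ibi_mean_ms = mean(day_ibi_means),
      true_daily_intensity = sum(intensity),
      true_daily_steps = sum(steps)))
  }

  # two questionnaire responses, same underlying class at both time points
  ucla <- do.call(rbind, lapply(tp, function(date) {
    social <- if (label == 1) sample(12:20, 1) else sample(6:11, 1)
    emotional <- sample(6:14, 1)
    si <- ucla_items_for_score(social)
    ei <- ucla_items_for_score(emotional)
    items <- integer(12)
    items[seq(1, 11, 2)] <- si   # odd items: social factor
    items[seq(2, 12, 2)] <- ei   # even items: emotional factor
    cbind(data.frame(participant_id = id, date = date),
          stats::setNames(as.data.frame(as.list(items)),
                          paste0("item_", 1:12)))
  }))

  structure(list(participant_id = id, true_label = label,
                 ppg_segments = ppg_segments, ibi_windows = ibi_windows,
                 sleep_nights = sleep, activity_records = activity,
                 ucla_responses = ucla,
                 ground_truth = list(label = label, days = gt_day,
                                     dropped_days = as.Date(character(0)))),
            class = "participant_bundle")
}

ceil_10min <- function(t) {
  s <- as.numeric(t)
  as.POSIXct(ceiling(s / 600) * 600, origin = "1970-01-01", tz = "UTC")
}

#' Remove whole days from a participant bundle
#'
#' Each day present in the bundle is independently dropped (all streams:
#' IBI/PPG, the night ending that day, activity records) with the given
#' probability; dropped days are recorded in the bundle's ground truth.
#'
#' @param bundle a `participant_bundle`.
#' @param missing_day_rate drop probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the thinned bundle.
#' @export
inject_missingness <- function(bundle, missing_day_rate, seed = 1L) {
  stopifnot(missing_day_rate >= 0, missing_day_rate <= 1)
  if (missing_day_rate == 0) return(bundle)
  days <- sort(unique(bundle$sleep_nights$date))
  drop <- with_seed(seed, runif(length(days)) < missing_day_rate)
  dropped <- days[drop]
  if (length(dropped)) {
    bundle$sleep_nights <-
      bundle$sleep_nights[!(bundle$sleep_nights$date %in% dropped), ,
                          drop = FALSE]
    act_day <- as.Date(bundle$activity_records$interval_start, tz = "UTC")
    bundle$activity_records <-
      bundle$activity_records[!(act_day %in% dropped), , drop = FALSE]
    if (length(bundle$ibi_windows)) {
      keep <- !vapply(bundle$ibi_windows,
                      function(w) w$date %in% dropped, logical(1))
      bundle$ibi_windows <- bundle$ibi_windows[keep]
    }
    if (length(bundle$ppg_segments)) {
      keep <- !vapply(bundle$ppg_segments, function(s)
        as.Date(s$start_time, tz = "UTC") %in% dropped, logical(1))
      bundle$ppg_segments <- bundle$ppg_segments[keep]
    }
  }
  bundle$ground_truth$dropped_days <- dropped
  bundle
}

#' Generate a synthetic cohort
#'
#' Produces one [participant bundle][generate_cohort] per participant:
#' PPG (or, in fast mode, interbeat-interval series for sleep-period
#' windows), nightly sleep summaries, 10-minute activity records, two
#' UCLA-12 responses (one 8-day window each), and a ground-truth record.
#' Exactly `round(n * prevalence)` participants are lonely; their daily
#' activity intensity and resting SDNN are scaled by the configured
#' multipliers and their hourly step profile is flattened.
#'
#' @param config a [cohort_config()].
#' @return list of `participant_bundle` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  n1 <- round(n * config$loneliness_prevalence)
  with_seed(config$seed, {
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    lapply(seq_len(n), function(i) {
      b <- generate_participant(sprintf("P%03d", i), labels[i], config)
      inject_missingness(b, config$missing_day_rate,
                         seed = config$seed + 104729L + i)
    })
  })
}
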