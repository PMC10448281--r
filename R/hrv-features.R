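#' Heart rate from a cleaned interbeat-interval series
#'
#' HR is the number of detected peaks per minute. When the analysis
#' window's span is known (the usual case: a 5-minute PPG window) the
#' peak count is divided by that span; for bare interval lists the span
#' is taken as the summed intervals.
#'
#' @param ibis an `lw_ibi_series` from [clean_ibis()].
#' @return HR in beats per minute, or `NA` for unusable windows.
#' @export
compute_hr <- function(ibis) {
  stopifnot(inherits(ibis, "lw_ibi_series"))
  if (!ibis$usable || ibis$n_peaks == 0) return(NA_real_)
  dur_min <- if (is.finite(ibis$window_duration_s)) {
    ibis$window_duration_s / 60
  } else {
    (sum(ibis$intervals) + mean(ibis$intervals)) / 60000
  }
  hr <- ibis$n_peaks / dur_min
  if (hr < 30 || hr > 220) return(NA_real_)
  hr
}

#' Time-domain HRV parameters
#'
#' AVNN is the mean of the retained (normal) intervals, SDNN their
#' population SD, and RMSSD the root mean square of differences between
#' *adjacent* retained intervals — pairs separated by a rejected beat do
#' not contribute.
#'
#' @param ibis an `lw_ibi_series`.
#' @return named vector `c(avnn, sdnn, rmssd)` in ms; `NA`s when fewer
#'   than two intervals (or no adjacent pair for RMSSD) survive cleaning.
#' @export
compute_time_domain <- function(ibis) {
  stopifnot(inherits(ibis, "lw_ibi_series"))
  iv <- ibis$intervals
  n <- length(iv)
  if (n < 2) return(c(avnn = NA_real_, sdnn = NA_real_, rmssd = NA_real_))
  avnn <- mean(iv)
  sdnn <- sqrt(mean((iv - avnn)^2))
  adj <- which(diff(ibis$index) == 1L)
  rmssd <- if (length(adj)) sqrt(mean((iv[adj + 1L] - iv[adj])^2)) else NA_real_
  c(avnn = avnn, sdnn = sdnn, rmssd = rmssd)
}

#' Frequency-domain HRV parameters
#'
#' Spectral power of the interval series in the low-frequency band
#' (0.04-0.15 Hz, sympathetic + parasympathetic) and high-frequency band
#' (0.15-0.4 Hz, respiratory/parasympathetic), estimated by
#' least-squares spectral analysis ([lomb_periodogram()]) directly on the
#' unevenly spaced beat times — no interpolation or resampling.
#'
#' @param ibis an `lw_ibi_series`.
#' @param lf_band,hf_band band edges in Hz.
#' @return named vector `c(lf, hf, lf_hf)`; powers in ms^2; `lf_hf` is
#'   `NA` when HF is (numerically) zero.
#' @export
compute_freq_domain <- function(ibis, lf_band = c(0.04, 0.15),
                                hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(ibis, "lw_ibi_series"))
  iv <- ibis$intervals
  t <- ibis$times_s
  out <- c(lf = NA_real_, hf = NA_real_, lf_hf = NA_real_)
  if (length(iv) < 10 || diff(range(t)) < 1 / lf_band[1]) return(out)
  if (stats::sd(iv) == 0) return(c(lf = 0, hf = 0, lf_hf = NA_real_))
  df <- 1 / diff(range(t))
  freq <- seq(lf_band[1], hf_band[2], by = df)   # one evaluation, two bands
  p <- 2 * .lomb_power(t, iv, freq) / length(iv)
  lf <- sum(p[freq <= lf_band[2]])
  hf <- sum(p[freq > lf_band[2] & freq >= hf_band[1]])
  c(lf = lf, hf = hf, lf_hf = if (hf > 1e-12) lf / hf else NA_real_)
}

#' All HR/HRV parameters of one window
#'
#' @param ibis an `lw_ibi_series`.
#' @return named vector `c(hr, avnn, sdnn, rmssd, lf, hf, lf_hf)`.
#' @export
hrv_record <- function(ibis) {
  c(hr = compute_hr(ibis), compute_time_domain(ibis), compute_freq_domain(ibis))
}

#' Select the nightly resting window
#'
#' The resting HR/HRV of a night is the record of the sleep-period
#' analysis window with the lowest heart rate; ties go to the earliest
#' window. Windows starting outside the sleep interval are ignored.
#'
#' @param night_windows data.frame with columns `start_time` (POSIXct)
#'   and the seven HRV columns of [hrv_record()].
#' @param sleep_onset,sleep_offset POSIXct bounds of the sleep interval.
#' @return the chosen row (one-row data.frame), or `NULL` when no
#'   reliable sleep-period window exists.
#' @export
select_resting <- function(night_windows, sleep_onset, sleep_offset) {
  if (is.null(night_windows) || nrow(night_windows) == 0) return(NULL)
  cand <- night_windows[!is.na(night_windows$hr) &
                          night_windows$start_time >= sleep_onset &
                          night_windows$start_time <= sleep_offset, ,
                        drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$hr, cand$start_time), , drop = FALSE]
  cand[1, , drop = FALSE]
}
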