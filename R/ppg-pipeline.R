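#' Raw PPG container
#'
#' A segment is one continuous recording bout of the wrist
#' photoplethysmogram; the study watch records 12-minute bouts every
#' other hour at 20 Hz. Shorter bouts are accepted but flagged.
#'
#' @param participant_id participant identifier.
#' @param start_time POSIXct start of the recording.
#' @param fs_hz sampling frequency, Hz.
#' @param samples numeric amplitude vector.
#' @return object of class `ppg_segment`.
#' @export
ppg_segment <- function(participant_id, start_time, fs_hz, samples) {
  stopifnot(fs_hz > 0, is.numeric(samples))
  structure(list(participant_id = participant_id,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 fs_hz = fs_hz, samples = as.numeric(samples),
                 short = length(samples) < 12 * 60 * fs_hz),
            class = "ppg_segment")
}

#' Split a PPG segment into 5-minute analysis windows
#'
#' Short-term HRV analysis uses non-overlapping 5-minute windows; a
#' trailing remainder shorter than the window is dropped (a 12-minute
#' bout therefore yields two windows).
#'
#' @param segment a [ppg_segment()].
#' @param window_s window length in seconds (default 300).
#' @return list of `ppg_window` objects with reliability `"unassessed"`.
#' @export
window_segment <- function(segment, window_s = 300) {
  stopifnot(inherits(segment, "ppg_segment"))
  n <- length(segment$samples)
  if (n == 0) stop("empty segment")
  wl <- round(window_s * segment$fs_hz)
  k <- n %/% wl
  lapply(seq_len(k), function(i) {
    off <- (i - 1L) * wl
    structure(list(participant_id = segment$participant_id,
                   start_time = segment$start_time + off / segment$fs_hz,
                   offset = off, fs_hz = segment$fs_hz,
                   samples = segment$samples[off + seq_len(wl)],
                   reliability = "unassessed"),
              class = "ppg_window")
  })
}

# ---- peak detection --------------------------------------------------------

#' Adaptive-threshold peak detection on a filtered pulse waveform
#'
#' Moving-average-based detector: the threshold is the 0.75 s moving
#' average of the signal raised by a percentage of the signal's amplitude
#' range; candidate percentages 0, 5, ..., 30 are tried and the one whose
#' interbeat intervals are most regular (minimum SD, subject to an
#' implied heart rate in 40-180 bpm) wins. Each run of supra-threshold
#' samples contributes its maximum as one peak.
#'
#' @param x filtered samples (use [bandpass()] first).
#' @param fs_hz sampling frequency in Hz.
#' @param ma_window_s moving-average window, seconds.
#' @param percentages candidate threshold raises, fraction of amplitude range.
#' @param hr_limits plausible implied-HR band, bpm.
#' @return integer vector of 1-based peak sample indices; empty (with
#'   attribute `warning`) when nothing plausible is found.
#' @export
detect_peaks <- function(x, fs_hz, ma_window_s = 0.75,
                         percentages = seq(0, 0.30, by = 0.05),
                         hr_limits = c(40, 180)) {
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0)
    return(structure(integer(0), warning = "flat or empty signal"))
  ma <- moving_average(x, round(ma_window_s * fs_hz))
  rng <- diff(range(x))
  best <- NULL
  best_sd <- Inf
  for (p in percentages) {
    peaks <- peaks_above(x, ma + p * rng)
    if (length(peaks) < 3) next
    ibis <- diff(peaks) / fs_hz
    hr <- 60 / mean(ibis)
    if (hr < hr_limits[1] || hr > hr_limits[2]) next
    s <- stats::sd(ibis)
    if (s < best_sd) {
      best_sd <- s
      best <- peaks
    }
  }
  if (is.null(best))
    return(structure(integer(0), warning = "no plausible peaks"))
  best
}

peaks_above <- function(x, thr) {
  above <- x > thr
  if (!any(above)) return(integer(0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(x[seg])]
  }, integer(1))
}

# ---- IBI cleaning ----------------------------------------------------------

#' Reject implausible interbeat intervals
#'
#' Two-stage error rejection of IBIs within one analysis window: an
#' absolute physiological band (default 300-2000 ms), then an iterated
#' relative band of +/-30 percent around the mean of the currently
#' retained intervals (the mean is recomputed after each rejection pass
#' until stable). Windows retaining fewer than `min_retained` intervals
#' are marked unusable and propagate as missing HRV.
#'
#' @param peak_times peak sample indices (with `fs_hz`) or `NULL` when
#'   `intervals` is given directly.
#' @param fs_hz sampling frequency of `peak_times`.
#' @param intervals raw IBIs in ms (alternative entry point, used by the
#'   generator's fast mode).
#' @param abs_band absolute plausibility band, ms.
#' @param rel_band relative band half-width around the window mean.
#' @param min_retained minimum retained intervals for a usable window.
#' @param window_duration_s known window span in seconds (for HR).
#' @return An `lw_ibi_series`: retained `intervals` (ms), their original
#'   `index`, beat `times_s`, a `rejected` data.frame with reasons,
#'   `n_peaks`, `usable`.
#' @export
clean_ibis <- function(peak_times = NULL, fs_hz = NULL, intervals = NULL,
                       abs_band = c(300, 2000), rel_band = 0.3,
                       min_retained = 10L, window_duration_s = NA_real_) {
  if (is.null(intervals)) {
    if (length(peak_times) < 2) stop("need at least 2 peaks")
    intervals <- diff(peak_times) / fs_hz * 1000
  }
  n <- length(intervals)
  reason <- rep(NA_character_, n)
  kept <- intervals >= abs_band[1] & intervals <= abs_band[2]
  reason[!kept] <- "absolute"
  repeat {
    if (!any(kept)) break
    m <- mean(intervals[kept])
    bad <- kept & (intervals < (1 - rel_band) * m |
                   intervals > (1 + rel_band) * m)
    if (!any(bad)) break
    kept[bad] <- FALSE
    reason[bad] <- "relative"
  }
  times <- cumsum(intervals) / 1000
  out <- structure(list(
    intervals = intervals[kept],
    index = which(kept),
    times_s = times[kept],
    rejected = data.frame(index = which(!kept),
                          interval = intervals[!kept],
                          reason = reason[!kept]),
    n_peaks = sum(kept) + 1L,
    window_duration_s = window_duration_s,
    usable = sum(kept) >= min_retained
  ), class = "lw_ibi_series")
  out
}

# ---- signal quality --------------------------------------------------------

#' Morphological features of a PPG window
#'
#' The quality gate scores windows by waveform morphology rather than by
#' amplitude alone: cycles are segmented at detected peaks, resampled to
#' a common length, and compared against the window's own template
#' (mean) cycle. Motion artifacts destroy the inter-cycle correlation
#' long before they change summary amplitudes.
#'
#' @param window a `ppg_window` (or numeric samples via `x`/`fs_hz`).
#' @param x,fs_hz alternative raw entry point.
#' @return named numeric vector: `template_cor` (mean Pearson correlation
#'   of cycles against the template), `amp_dispersion` (CV of cycle
#'   peak-to-trough amplitudes), `implausible_frac` (fraction of cycle
#'   lengths outside 300-2000 ms), `snr_db` (in-band to out-of-band power
#'   ratio), `cycle_cv` (CV of cycle lengths).
#' @export
extract_morphology_features <- function(window = NULL, x = NULL, fs_hz = NULL) {
  if (!is.null(window)) {
    stopifnot(inherits(window, "ppg_window"))
    x <- window$samples
    fs_hz <- window$fs_hz
  }
  if (stats::sd(x) == 0) stop("degenerate (flat) window")
  filt <- bandpass(x, fs_hz)
  resid <- (x - mean(x)) - filt
  snr_db <- 10 * log10(stats::var(filt) / (stats::var(resid) + 1e-12))
  peaks <- detect_peaks(filt, fs_hz)
  if (length(peaks) < 4) {
    return(c(template_cor = 0, amp_dispersion = 10, implausible_frac = 1,
             snr_db = snr_db, cycle_cv = 10))
  }
  cyc_len_ms <- diff(peaks) / fs_hz * 1000
  L <- 30L
  # cycle content comes from the raw (centred) signal in fixed-length
  # windows centred on each detected peak: filtered white noise is
  # quasi-periodic and peak-to-peak segmentation of it would fake
  # inter-cycle similarity
  raw <- x - mean(x)
  half <- max(2L, floor(stats::median(diff(peaks)) / 2))
  ok <- peaks[peaks - half >= 1 & peaks + half <= length(raw)]
  if (length(ok) < 4) {
    return(c(template_cor = 0, amp_dispersion = 10, implausible_frac = 1,
             snr_db = snr_db, cycle_cv = 10))
  }
  cycles <- vapply(ok, function(p) {
    seg <- raw[(p - half):(p + half)]
    stats::approx(seq_along(seg), seg, n = L)$y
  }, numeric(L))
  template <- rowMeans(cycles)
  # the centre samples are excluded from the correlation: cycles are
  # aligned on detected maxima, so even pure noise is elevated there
  keep_idx <- setdiff(seq_len(L), (L %/% 2 - 1):(L %/% 2 + 2))
  cors <- apply(cycles, 2, function(cc) {
    cc <- cc[keep_idx]; tpl <- template[keep_idx]
    if (stats::sd(cc) == 0 || stats::sd(tpl) == 0) return(0)
    stats::cor(cc, tpl)
  })
  amps <- apply(cycles, 2, function(cc) diff(range(cc)))
  c(template_cor = mean(cors),
    amp_dispersion = stats::sd(amps) / (mean(amps) + 1e-12),
    implausible_frac = mean(cyc_len_ms < 300 | cyc_len_ms > 2000),
    snr_db = snr_db,
    cycle_cv = stats::sd(cyc_len_ms) / mean(cyc_len_ms))
}

#' Train the one-class signal-quality model
#'
#' A one-class support vector machine (RBF kernel, nu-parameterised) is
#' fit on morphological features of windows assumed reliable; the dual
#' quadratic program is solved exactly with `quadprog`. At most a
#' fraction `nu` of the training windows fall outside the learned
#' boundary.
#'
#' @param reliable_windows list of `ppg_window` objects, or a numeric
#'   feature matrix (rows = windows) already produced by
#'   [extract_morphology_features()].
#' @param nu upper bound on the training outlier fraction (default 0.05).
#' @param gamma RBF width; default `1/d` on standardised features.
#' @param min_windows minimum training-set size.
#' @return object of class `lw_quality_model`.
#' @export
train_quality_model <- function(reliable_windows, nu = 0.05, gamma = NULL,
                                min_windows = 50L) {
  feats <- if (is.matrix(reliable_windows)) reliable_windows else
    t(vapply(reliable_windows, function(w) extract_morphology_features(w),
             numeric(5)))
  n <- nrow(feats)
  if (n < min_windows)
    stop("need at least ", min_windows, " reliable windows to train")
  center <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(feats, 2, center), 2, scl, "/")
  d <- ncol(z)
  if (is.null(gamma)) gamma <- 1 / d
  K <- rbf_kernel(z, z, gamma)
  up <- 1 / (nu * n)
  sol <- quadprog::solve.QP(
    Dmat = K + diag(1e-8, n), dvec = rep(0, n),
    Amat = cbind(rep(1, n), diag(n), -diag(n)),
    bvec = c(1, rep(0, n), rep(-up, n)), meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), up)
  f <- as.numeric(K %*% alpha)
  margin <- which(alpha > 1e-7 & alpha < up - 1e-7)
  rho <- if (length(margin)) mean(f[margin]) else max(f[alpha > 1e-7])
  model <- structure(list(alpha = alpha, sv = z, gamma = gamma, rho = rho,
                          nu = nu, center = center, scale = scl,
                          feature_names = colnames(feats)),
                     class = "lw_quality_model")
  model$train_inlier_fraction <- mean(f - rho >= -1e-9)
  model
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

quality_score <- function(model, feats) {
  z <- sweep(sweep(rbind(feats), 2, model$center), 2, model$scale, "/")
  as.numeric(rbf_kernel(z, model$sv, model$gamma) %*% model$alpha) - model$rho
}

#' Classify a PPG window as reliable or unreliable
#'
#' Degenerate (flat) windows are unreliable by definition; otherwise the
#' trained one-class model scores the window's morphology.
#'
#' @param window a `ppg_window`.
#' @param model an [train_quality_model()] fit.
#' @return the window with `reliability` set to `"reliable"` or
#'   `"unreliable"` and a `quality_score` element.
#' @export
assess_quality <- function(window, model) {
  stopifnot(inherits(window, "ppg_window"), inherits(model, "lw_quality_model"))
  if (stats::sd(window$samples) == 0) {
    window$reliability <- "unreliable"
    window$quality_score <- -Inf
    return(window)
  }
  feats <- extract_morphology_features(window)
  s <- quality_score(model, feats)
  window$reliability <- if (s >= -1e-9) "reliable" else "unreliable"
  window$quality_score <- s
  window
}

#' Run the full PPG stage on one segment
#'
#' Filters the whole segment (zero phase), splits it into 5-minute
#' windows, applies the quality gate when a model is supplied, detects
#' peaks and cleans IBIs per reliable window.
#'
#' @param segment a [ppg_segment()].
#' @param quality_model optional `lw_quality_model`; without it all
#'   windows are treated as reliable (useful for clean synthetic data).
#' @param ... passed to [clean_ibis()].
#' @return list of per-window results: `window` (with verdict), `ibis`
#'   (`lw_ibi_series` or `NULL` for unreliable/unusable windows).
#' @export
process_segment <- function(segment, quality_model = NULL, ...) {
  filtered <- bandpass(segment$samples, segment$fs_hz)
  windows <- window_segment(segment)
  lapply(windows, function(w) {
    if (!is.null(quality_model)) w <- assess_quality(w, quality_model)
    else w$reliability <- "reliable"
    if (w$reliability != "reliable") return(list(window = w, ibis = NULL))
    fw <- filtered[w$offset + seq_along(w$samples)]
    peaks <- detect_peaks(fw, w$fs_hz)
    if (length(peaks) < 2) return(list(window = w, ibis = NULL))
    ib <- clean_ibis(peaks, w$fs_hz,
                     window_duration_s = length(w$samples) / w$fs_hz, ...)
    list(window = w, ibis = if (ib$usable) ib else NULL)
  })
}
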