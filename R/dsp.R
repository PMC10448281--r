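#' @useDynLib lonewatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd var approx rbinom rnorm runif rlnorm
#'   rpois setNames cor aggregate plogis
#' @importFrom utils read.csv write.csv
NULL

# ---- minimal IIR machinery -------------------------------------------------
# Second-order Butterworth sections designed by bilinear transform. Only what
# the PPG band [0.7, 3.5] Hz at fs = 20 Hz needs; coefficients cross-checked
# against reference DSP implementations during development.

butter2_coefs <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  k <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * k + k^2)
  a <- c(1, 2 * (k^2 - 1) * norm, (1 - sqrt(2) * k + k^2) * norm)
  b <- if (type == "low") c(k^2, 2 * k^2, k^2) * norm else c(1, -2, 1) * norm
  list(b = b, a = a)
}

iir_filter <- function(x, b, a) {
  # direct form I: convolution part via stats::filter, then the recursion
  n <- length(x)
  xb <- stats::filter(c(rep(0, 2), x), b, method = "convolution", sides = 1)
  xb <- as.numeric(xb)[-(1:2)]
  as.numeric(stats::filter(xb, -a[-1], method = "recursive"))
}

filtfilt2 <- function(x, b, a) {
  n <- length(x)
  pad <- min(n - 1, 60L)
  if (pad > 0) {
    # odd (reflective) extension damps startup transients at both ends
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- iir_filter(xe, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Zero-phase bandpass filter for pulse waveforms
#'
#' Applies a second-order Butterworth high-pass and low-pass cascade
#' forward and backward (zero phase, so peak timing is preserved). The
#' default band 0.7-3.5 Hz brackets the human cardiac fundamental at rest
#' and removes baseline wander and high-frequency noise.
#'
#' @param x numeric sample vector.
#' @param fs_hz sampling frequency in Hz.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency.
#' @return filtered samples, same length as `x`.
#' @examples
#' t <- seq(0, 10, by = 1 / 20)
#' x <- sin(2 * pi * 1.2 * t) + sin(2 * pi * 0.2 * t)
#' y <- bandpass(x, 20)
#' @export
bandpass <- function(x, fs_hz, low_hz = 0.7, high_hz = 3.5) {
  if (high_hz >= fs_hz / 2)
    stop("sampling rate too low for the requested band")
  if (low_hz <= 0 || low_hz >= high_hz) stop("invalid band edges")
  if (length(x) < 10) stop("signal too short to filter")
  hp <- butter2_coefs(low_hz, fs_hz, "high")
  lp <- butter2_coefs(high_hz, fs_hz, "low")
  filtfilt2(filtfilt2(x, hp$b, hp$a), lp$b, lp$a)
}

moving_average <- function(x, width) {
  # centred moving mean, edges use the available samples
  n <- length(x)
  half <- max(1L, floor(width / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Least-squares spectral estimate used for the frequency-domain HRV
#' parameters: interbeat intervals are naturally sampled at the (uneven)
#' beat times, and the Lomb-Scargle estimator avoids the interpolation
#' bias a resampling approach would introduce at low PPG sampling rates.
#'
#' @param t sample times in seconds (strictly increasing).
#' @param x sample values (the series is centred internally).
#' @param freq frequencies (Hz) at which to evaluate the spectrum.
#' @return data.frame with columns `freq` and `power`; `power` is scaled so
#'   that the sum of `2 * power / n` over frequencies spaced `1/span`
#'   apart approximates the series variance (classical periodogram units).
#' @export
lomb_periodogram <- function(t, x, freq) {
  stopifnot(length(t) == length(x), length(t) >= 4)
  data.frame(freq = freq, power = .lomb_power(t, x, freq))
}

.lomb_power <- function(t, x, freq) {
  x <- x - mean(x)
  n <- length(x)
  w <- 2 * pi * freq                      # one column per frequency
  wt <- outer(t, w)
  tau_w <- atan2(colSums(sin(2 * wt)), colSums(cos(2 * wt))) / 2
  arg <- sweep(wt, 2, tau_w)
  ct <- cos(arg); st <- sin(arg)
  c2 <- colSums(ct^2); s2 <- colSums(st^2)
  xc <- colSums(x * ct); xs <- colSums(x * st)
  0.5 * (ifelse(c2 > 0, xc^2 / c2, 0) + ifelse(s2 > 0, xs^2 / s2, 0))
}

band_power <- function(t, x, band, df = NULL) {
  # integrated variance (units of x^2) attributable to the band
  span <- diff(range(t))
  if (is.null(df)) df <- 1 / span
  freq <- seq(band[1], band[2], by = df)
  sum(2 * .lomb_power(t, x, freq) / length(x))
}
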