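test_that("window_segment cuts 5-minute windows and drops the remainder", {
  fs <- 20
  seg12 <- ppg_segment("P1", "2023-01-01 08:00:00", fs, sin(seq_len(12 * 60 * fs)))
  w <- window_segment(seg12)
  expect_length(w, 2)                      # 12 min -> 2 windows, 2 min dropped
  expect_true(all(vapply(w, function(x) length(x$samples), 0L) == 300 * fs))
  expect_equal(w[[2]]$offset, 300 * fs)
  expect_length(window_segment(ppg_segment("P1", "2023-01-01", fs,
                                           seq_len(5 * 60 * fs))), 1)
  expect_length(window_segment(ppg_segment("P1", "2023-01-01", fs,
                                           seq_len(4 * 60 * fs))), 0)
  expect_error(window_segment(ppg_segment("P1", "2023-01-01", fs, numeric(0))),
               "empty")
})

test_that("windowing conserves samples", {
  fs <- 20
  for (mins in c(5, 7, 12, 13)) {
    n <- mins * 60 * fs
    seg <- ppg_segment("P1", "2023-01-01", fs, rnorm(n))
    w <- window_segment(seg)
    used <- sum(vapply(w, function(x) length(x$samples), 0L))
    expect_equal(used + n %% (300 * fs), n)
  }
})

test_that("bandpass meets its passband/stopband contract", {
  fs <- 20
  t <- seq(0, 60, by = 1 / fs)
  core <- 200:1000  # away from the edges
  gain_db <- function(f) {
    x <- sin(2 * pi * f * t)
    20 * log10(sd(bandpass(x, fs)[core]) / sd(x[core]))
  }
  expect_lt(gain_db(0.2), -20)
  expect_gt(gain_db(1.2), -3)
  expect_lt(gain_db(7), -20)   # one octave above the 3.5 Hz edge
  expect_equal(bandpass(rep(0, 1200), fs), rep(0, 1200))
  expect_error(bandpass(rnorm(100), fs_hz = 6), "too low")
})

peaks_in <- function(x) which(diff(sign(diff(x))) == -2) + 1L

test_that("bandpass is zero-phase: in-band tone keeps its peak positions", {
  fs <- 20
  t <- seq(0, 30, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  y <- bandpass(x, fs)
  px <- peaks_in(x)
  py <- peaks_in(y)
  common <- intersect(px, (min(px) + 50):(max(px) - 50))
  expect_true(all(vapply(common, function(p) min(abs(py - p)), 0) <= 1))
})

test_that("detect_peaks recovers ground-truth beats on clean signal", {
  iv <- generate_ibi_series(60, 30, 0.25, 300, seed = 4)
  seg <- generate_ppg(iv, 20, 0)
  pk <- detect_peaks(bandpass(seg$samples, 20), 20)
  expect_true(abs(length(pk) - 300) <= 3)
  tp <- attr(seg, "true_peak_times_s")
  pt <- (pk - 1) / 20
  err <- vapply(tp, function(x) min(abs(pt - x)), 0)
  expect_true(all(err <= 1 / 20 + 1e-9))
  expect_length(detect_peaks(rep(1, 6000), 20), 0)
})

test_that("clean_ibis applies absolute then iterated relative rejection", {
  ib <- make_ibis(c(rep(1000, 10), 400))
  expect_equal(ib$intervals, rep(1000, 10))
  expect_equal(ib$rejected$reason, "relative")
  expect_true(ib$usable)

  ib2 <- make_ibis(rep(800, 15))
  expect_equal(nrow(ib2$rejected), 0)

  ib3 <- make_ibis(rep(250, 20))      # all below the absolute band
  expect_length(ib3$intervals, 0)
  expect_false(ib3$usable)
  expect_true(all(ib3$rejected$reason == "absolute"))

  expect_error(clean_ibis(peak_times = c(5), fs_hz = 20), "at least 2")
})

test_that("clean_ibis is idempotent", {
  set.seed(9)
  for (i in 1:20) {
    iv <- c(rnorm(30, 900, 80), sample(c(250, 420, 1600, 2500), 4))
    once <- make_ibis(iv)
    twice <- make_ibis(once$intervals)
    expect_equal(twice$intervals, once$intervals)
    expect_equal(nrow(twice$rejected), 0)
  }
})

test_that("morphology features separate clean pulse from noise", {
  iv <- generate_ibi_series(70, 40, 0.25, 300, seed = 2)
  seg <- generate_ppg(iv, 20, 0)
  f_clean <- extract_morphology_features(x = seg$samples, fs_hz = 20)
  expect_gt(f_clean[["template_cor"]], 0.9)
  set.seed(3)
  f_noise <- extract_morphology_features(x = rnorm(6000), fs_hz = 20)
  expect_lt(f_noise[["template_cor"]], 0.5)
  expect_error(extract_morphology_features(x = rep(2, 6000), fs_hz = 20),
               "degenerate")
})

make_quality_windows <- function(n, noise, seed0) {
  t(vapply(seq_len(n), function(i) {
    iv <- generate_ibi_series(runif(1, 55, 90), 40, 0.25, 300,
                              seed = seed0 + i)
    seg <- generate_ppg(iv, 20, noise, seed = seed0 + 500 + i)
    extract_morphology_features(x = seg$samples[1:6000], fs_hz = 20)
  }, numeric(5)))
}

test_that("one-class quality model gates artifact windows", {
  set.seed(11)
  train <- make_quality_windows(60, 0.03, 3000)
  model <- train_quality_model(train, nu = 0.05)
  expect_gte(model$train_inlier_fraction, 0.95)

  art <- make_quality_windows(15, 0.8, 4000)
  expect_gte(mean(quality_score(model, art) < 0), 0.9)

  expect_error(train_quality_model(train[1:10, ], nu = 0.05), "at least")

  # flat window is unreliable by definition
  w <- structure(list(participant_id = "P", start_time = Sys.time(),
                      offset = 0L, fs_hz = 20, samples = rep(1, 6000),
                      reliability = "unassessed"), class = "ppg_window")
  expect_equal(assess_quality(w, model)$reliability, "unreliable")
})

test_that("quality gate is monotone in artifact amplitude", {
  set.seed(12)
  train <- make_quality_windows(60, 0.03, 6000)
  model <- train_quality_model(train, nu = 0.05)
  frac_reliable <- vapply(c(0.05, 0.3, 0.9), function(noise) {
    w <- make_quality_windows(10, noise, 7000)
    mean(quality_score(model, w) >= 0)
  }, 0)
  expect_true(all(diff(frac_reliable) <= 0))
})
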