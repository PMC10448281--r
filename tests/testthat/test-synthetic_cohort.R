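test_that("cohort_config validates its inputs", {
  expect_error(cohort_config(n_participants = 1), "at least 2")
  expect_error(cohort_config(loneliness_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(missing_day_rate = -0.1), "\\[0, 1\\]")
  expect_error(cohort_config(effect_multipliers = list(bogus = 1)), "unknown")
  cfg <- cohort_config(10, 0.3, seed = 7)
  expect_equal(cfg$effect_multipliers$activity_intensity, 0.6)
})

test_that("prevalence rounds to the planted label count", {
  cfg <- cohort_config(10, 0.3, fast_mode = TRUE, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(sum(vapply(cohort, `[[`, 0L, "true_label")), 3L)
})

test_that("same config twice gives byte-identical serialised cohorts", {
  cfg <- cohort_config(3, 0.5, missing_day_rate = 0.2, fast_mode = TRUE,
                       seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("lonely group's emitted intensity is reduced, monotonically in
           the multiplier", {
  mean_int_by_group <- function(mult) {
    cfg <- cohort_config(8, 0.5, fast_mode = TRUE, seed = 17,
                         effect_multipliers = list(activity_intensity = mult))
    cohort <- generate_cohort(cfg)
    daily <- vapply(cohort, function(b) {
      sum(b$activity_records$intensity) /
        length(unique(as.Date(b$activity_records$interval_start)))
    }, 0)
    lab <- vapply(cohort, `[[`, 0L, "true_label")
    c(lonely = mean(daily[lab == 1]), non = mean(daily[lab == 0]))
  }
  m06 <- mean_int_by_group(0.6)
  expect_lt(m06[["lonely"]], m06[["non"]])
  m03 <- mean_int_by_group(0.3)
  expect_lt(m03[["lonely"]], m06[["lonely"]])   # holding the seed fixed
})

test_that("generate_ibi_series meets its contracts", {
  iv0 <- generate_ibi_series(60, 0, duration_s = 300, seed = 1)
  expect_equal(iv0, rep(1000, 300))

  iv <- generate_ibi_series(75, 50, 0.25, 300, seed = 2)
  expect_lt(abs(sum(iv) - 300000), 2 * mean(iv))
  expect_lt(abs(mean(iv) - 60000 / 75) / (60000 / 75), 0.02)
  expect_lt(abs(sd(iv) - 50) / 50, 0.2)

  # spectral peak at the modulation frequency
  p <- lomb_periodogram(cumsum(iv) / 1000, iv, seq(0.02, 0.45, by = 0.005))
  expect_lt(abs(p$freq[which.max(p$power)] - 0.25), 0.02)

  expect_error(generate_ibi_series(25, 10), "out of range")
  expect_error(generate_ibi_series(60, 1200), "exceeds")
  expect_error(generate_ibi_series(60, 10, duration_s = 0), "positive")
})

test_that("generate_ppg produces aligned true peaks and right sample count", {
  iv <- generate_ibi_series(60, 0, duration_s = 300, seed = 1)
  seg <- generate_ppg(iv, 20, 0)
  expect_length(seg$samples, 6000)

  # noise-free 60 bpm: systolic maxima (the dicrotic bump is a genuine
  # secondary local maximum) spaced 1000 ms within one sample period
  x <- seg$samples
  loc <- which(diff(sign(diff(x))) == -2) + 1L
  loc <- loc[x[loc] > 0.5]
  gaps <- diff(loc) / 20 * 1000
  expect_true(all(abs(gaps - 1000) <= 50 + 1e-9))

  # detected clean-waveform maxima align with stored truth within 1 sample
  tp <- attr(seg, "true_peak_times_s")
  pt <- (loc - 1) / 20
  err <- vapply(tp[-1], function(z) min(abs(pt - z)), 0)
  expect_true(all(err <= 1 / 20 + 1e-9))

  expect_error(generate_ppg(numeric(0), 20), "empty")
  expect_error(generate_ppg(iv, 6), "undersamples")
})

test_that("inject_missingness drops whole days and logs them", {
  cfg <- cohort_config(2, 0.5, missing_day_rate = 0, fast_mode = TRUE, seed = 3)
  b <- generate_cohort(cfg)[[1]]

  expect_identical(inject_missingness(b, 0, seed = 5), b)

  gone <- inject_missingness(b, 1, seed = 5)
  expect_equal(nrow(gone$sleep_nights), 0)
  expect_equal(nrow(gone$activity_records), 0)
  expect_length(gone$ibi_windows, 0)
  expect_length(gone$ground_truth$dropped_days, 16)

  half <- inject_missingness(b, 0.5, seed = 6)
  dropped <- half$ground_truth$dropped_days
  expect_equal(sort(unique(c(half$sleep_nights$date, dropped))),
               sort(unique(b$sleep_nights$date)))
  act_days <- unique(as.Date(half$activity_records$interval_start))
  expect_length(intersect(act_days, dropped), 0)
})

test_that("fast-mode bundles carry the expected stream shapes", {
  cfg <- cohort_config(2, 0.5, missing_day_rate = 0, fast_mode = TRUE, seed = 8)
  b <- generate_cohort(cfg)[[1]]
  expect_equal(nrow(b$sleep_nights), 16)       # 2 windows x 8 nights
  expect_equal(nrow(b$ucla_responses), 2)
  expect_length(b$ppg_segments, 0)
  expect_gt(length(b$ibi_windows), 0)
  # ucla items reproduce the planted label at both time points
  for (i in 1:2) {
    sc <- score_ucla(as.numeric(b$ucla_responses[i, paste0("item_", 1:12)]))
    expect_equal(loneliness_label(sc[["social_score"]]), b$true_label)
  }
})

test_that("cohort CSV round-trip preserves the streams", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(2, 0.5, fast_mode = TRUE, seed = 12)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c("sleep.csv", "activity.csv",
                                               "ucla.csv", "ibi.csv",
                                               "ground_truth.json")))))
  back <- read_cohort(dir)
  expect_length(back, 2)
  b0 <- cohort[[1]]; b1 <- back[[1]]
  expect_equal(nrow(b1$sleep_nights), nrow(b0$sleep_nights))
  expect_equal(b1$sleep_nights$tst_min, b0$sleep_nights$tst_min,
               tolerance = 1e-6)
  expect_equal(length(b1$ibi_windows), length(b0$ibi_windows))
  expect_equal(b1$ibi_windows[[1]]$intervals, b0$ibi_windows[[1]]$intervals,
               tolerance = 1e-6)
  # extraction on the round-tripped bundle agrees with the original
  f0 <- extract_daily_features(b0)
  f1 <- extract_daily_features(b1)
  expect_equal(f1$daily$sdnn, f0$daily$sdnn, tolerance = 1e-4)
  expect_equal(f1$summary$valid, f0$summary$valid)
})
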