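# Shared fixtures, built in code. Kept tiny: most tests construct their own
# inputs; the cached cohort below is reused by the tests that need a whole
# extracted cohort (generation + extraction dominate test runtime).

make_ibis <- function(intervals, window_duration_s = NA_real_) {
  clean_ibis(intervals = intervals, window_duration_s = window_duration_s)
}

# one small fast-mode cohort + extracted features, computed once per run
small_cohort_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_participants = 12, loneliness_prevalence = 0.5,
                           missing_day_rate = 0.1, fast_mode = TRUE, seed = 42)
      cohort <- generate_cohort(cfg)
      feats <- extract_cohort_features(cohort)
      built <- build_samples(feats$daily, feats$summary, feats$ucla)
      ds <- assemble(built$samples)
      cache <<- list(config = cfg, cohort = cohort, feats = feats,
                     built = built, datasets = ds)
    }
    cache
  }
})

# deterministic activity records: `steps_by_hour` named by hour (0-23),
# each hour filled with six 10-minute records of steps/6
make_activity_records <- function(day, steps_by_hour, id = "P1") {
  day <- as.Date(day)
  rows <- lapply(names(steps_by_hour), function(h) {
    start <- as.POSIXct(paste(day, sprintf("%02d:00:00", as.integer(h))),
                        tz = "UTC") + seq(0, 50, by = 10) * 60
    s <- rep(steps_by_hour[[h]] / 6, 6)
    data.frame(participant_id = id, interval_start = start, steps = s,
               walking_steps = 0.8 * s, running_steps = 0,
               distance_m = 0.7 * s, active_min = pmin(10, s / 110),
               intensity = s / 1000)
  })
  do.call(rbind, rows)
}
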