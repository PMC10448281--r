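#!/usr/bin/env Rscript
# Regenerates the deterministic 5-participant builder fixture under
# inst/extdata/builder_fixture/. The fixture exercises every rule of the
# sample builder:
#   P1: 8 valid days, lonely (social 14)            -> retained, no imputation
#   P2: 4 valid days, nonlonely (social 8)          -> retained, imputation
#   P3: 3 valid days                                -> excluded (< 4 rule)
#   P4: 599/600-minute wear boundary, social 12     -> retained, label boundary
#   P5: 6 valid days but HRV missing on all days    -> dropped from
#       HRV-requiring datasets only
# Feature values are synthetic and formulaic (value = column index + day/10)
# so imputed cells are hand-checkable. The manifest holds the expected
# outcomes, derived by applying the stated rules by hand.

library(lonewatch)

dates <- seq(as.Date("2023-03-01"), as.Date("2023-03-08"), by = "day")
feat_names <- unlist(feature_groups(), use.names = FALSE)
hrv_names <- feature_groups()$hrv

mk_daily <- function(id, present_days, hrv_missing = FALSE, sdnn_vals = NULL) {
  rows <- lapply(seq_along(dates), function(i) {
    v <- setNames(seq_along(feat_names) + i / 10, feat_names)
    if (!is.null(sdnn_vals)) v["sdnn"] <- sdnn_vals[i]
    if (hrv_missing) v[hrv_names] <- NA
    if (!(i %in% present_days)) v[] <- NA
    cbind(data.frame(participant_id = id, date = dates[i]),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}

mk_summary <- function(id, wear, sleep_ok) {
  data.frame(participant_id = id, date = dates, wear_min_awake = wear,
             has_valid_sleep = sleep_ok,
             valid = is_valid_day(wear, sleep_ok))
}

daily <- rbind(
  mk_daily("P1", 1:8),
  mk_daily("P2", 1:4, sdnn_vals = c(50, 60, 40, 50, NA, NA, NA, NA)),
  mk_daily("P3", 1:3),
  mk_daily("P4", c(1, 2, 4, 6, 8)),
  mk_daily("P5", c(1:3, 5:7), hrv_missing = TRUE))

summary <- rbind(
  mk_summary("P1", rep(720, 8), rep(TRUE, 8)),
  mk_summary("P2", c(rep(650, 4), rep(0, 4)), c(rep(TRUE, 4), rep(FALSE, 4))),
  mk_summary("P3", c(650, 600, 700, rep(599, 5)), rep(TRUE, 8)),
  mk_summary("P4", c(600, 600, 599, 600, 599, 600, 599, 600),
             rep(TRUE, 8)),
  mk_summary("P5", rep(700, 8),
             c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)))

# item vectors chosen so odd (social) items sum to the target score
mk_items <- function(social, emotional) {
  items <- integer(12)
  base <- function(score) {
    it <- rep(1L, 6); rem <- score - 6L; j <- 1L
    while (rem > 0L) { add <- min(3L, rem); it[j] <- 1L + add
      rem <- rem - add; j <- j + 1L }
    it
  }
  items[seq(1, 11, 2)] <- base(social)
  items[seq(2, 12, 2)] <- base(emotional)
  items
}

ucla <- do.call(rbind, Map(function(id, social) {
  cbind(data.frame(participant_id = id, date = as.Date("2023-03-08")),
        setNames(as.data.frame(as.list(mk_items(social, 9))),
                 paste0("item_", 1:12)))
}, c("P1", "P2", "P3", "P4", "P5"), c(14, 8, 15, 12, 10)))

out <- file.path("inst", "extdata", "builder_fixture")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(daily, file.path(out, "daily_features.csv"), row.names = FALSE)
write.csv(summary, file.path(out, "day_summary.csv"), row.names = FALSE)
write.csv(ucla, file.path(out, "ucla.csv"), row.names = FALSE)

manifest <- list(
  n_responses = 5,
  retained = c("P1", "P2", "P4", "P5"),
  excluded = list(list(participant_id = "P3", reason = "only 3 valid days")),
  labels = list(P1 = 1, P2 = 0, P4 = 1, P5 = 0),
  valid_day_flags = list(
    P1 = rep(TRUE, 8),
    P2 = c(rep(TRUE, 4), rep(FALSE, 4)),
    P3 = c(TRUE, TRUE, TRUE, rep(FALSE, 5)),
    P4 = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    P5 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)),
  valid_day_counts = list(P1 = 8, P2 = 4, P3 = 3, P4 = 5, P5 = 6),
  # P2's sdnn: observed {50, 60, 40, 50} -> missing days filled with 50
  imputed = list(participant_id = "P2", feature = "sdnn",
                 days_filled = 5:8, value = 50, collapsed = 50),
  # P5 has no HRV at all -> dropped from datasets requiring the HRV group
  dataset_shapes = list(
    sleep = c(4, 6), hrv = c(3, 7), pa = c(4, 28),
    `sleep+hrv` = c(3, 13), `sleep+pa` = c(4, 34), `hrv+pa` = c(3, 35),
    all = c(3, 41)))
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("fixture written to", out, "\n")
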