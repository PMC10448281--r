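test_that("score_ucla sums the six items of each factor", {
  expect_equal(unname(score_ucla(rep(1, 12))), c(6, 6))
  expect_equal(unname(score_ucla(rep(4, 12))), c(24, 24))
  items <- rep(1, 12); items[seq(1, 11, 2)] <- 2
  expect_equal(score_ucla(items)[["social_score"]], 12)
  items[1] <- NA
  expect_true(is.na(score_ucla(items)[["social_score"]]))
  expect_false(is.na(score_ucla(items)[["emotional_score"]]))
})

test_that("loneliness label is >= 12 on the social score", {
  expect_equal(loneliness_label(12), 1L)
  expect_equal(loneliness_label(11), 0L)
  expect_equal(loneliness_label(6), 0L)
  expect_equal(loneliness_label(24), 1L)
  expect_error(loneliness_label(25), "outside")
  expect_error(loneliness_label(5), "outside")
})

test_that("labeling is monotone in any social item", {
  set.seed(13)
  for (i in 1:50) {
    items <- sample(1:4, 12, replace = TRUE)
    l0 <- loneliness_label(score_ucla(items)[["social_score"]])
    j <- sample(seq(1, 11, 2), 1)
    if (items[j] < 4) {
      items[j] <- items[j] + 1
      l1 <- loneliness_label(score_ucla(items)[["social_score"]])
      expect_gte(l1, l0)
    }
  }
})

test_that("valid-day rule requires 10 awake-worn hours and valid sleep", {
  expect_true(is_valid_day(600, TRUE))
  expect_false(is_valid_day(599, TRUE))
  expect_false(is_valid_day(700, FALSE))
  expect_true(is_valid_day(960, TRUE))
})

# hand-built daily table: 8 days, two features observed on a known pattern
mini_world <- function(valid_pattern, sdnn_vals = NULL) {
  dates <- seq(as.Date("2023-03-01"), as.Date("2023-03-08"), by = "day")
  feat_names <- unlist(feature_groups(), use.names = FALSE)
  daily <- cbind(data.frame(participant_id = "P1", date = dates),
                 as.data.frame(matrix(1, 8, length(feat_names),
                                      dimnames = list(NULL, feat_names))))
  daily$step_counts <- c(8000, 8000, 8000, 8000, 6000, 6000, 6000, 6000)
  if (!is.null(sdnn_vals)) daily$sdnn <- sdnn_vals
  summary <- data.frame(participant_id = "P1", date = dates,
                        wear_min_awake = ifelse(valid_pattern, 700, 0),
                        has_valid_sleep = valid_pattern,
                        valid = valid_pattern)
  list(daily = daily, summary = summary)
}

test_that("build_sample enforces the >= 4 valid day rule", {
  w3 <- mini_world(c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  s3 <- build_sample("P1", "2023-03-08", 14, w3$daily, w3$summary)
  expect_s3_class(s3, "excluded_sample")
  expect_match(attr(s3, "reason"), "3 valid")

  w4 <- mini_world(c(rep(TRUE, 4), rep(FALSE, 4)))
  s4 <- build_sample("P1", "2023-03-08", 14, w4$daily, w4$summary)
  expect_s3_class(s4, "data_sample")
  expect_equal(s4$valid_day_count, 4)
  expect_equal(s4$label, 1L)
  expect_true(all(is.na(s4$days[5:8, ])))

  w8 <- mini_world(rep(TRUE, 8))
  s8 <- build_sample("P1", "2023-03-08", 8, w8$daily, w8$summary)
  expect_equal(s8$valid_day_count, 8)
  expect_equal(s8$label, 0L)
  expect_identical(impute_sample(s8)$days, s8$days)  # no-op on complete data
})

test_that("imputation fills with within-sample means and conserves them", {
  w <- mini_world(c(rep(TRUE, 4), rep(FALSE, 4)),
                  sdnn_vals = c(50, 60, 40, 50, 99, 99, 99, 99))
  s <- impute_sample(build_sample("P1", "2023-03-08", 14, w$daily, w$summary))
  expect_equal(unname(s$days[5:8, "sdnn"]), rep(50, 4))  # mean(50,60,40,50)
  expect_equal(unname(s$days[1:4, "sdnn"]), c(50, 60, 40, 50))
  # conservation: mean over all days equals mean over observed days
  expect_equal(mean(s$days[, "sdnn"]), 50)
  expect_length(s$all_missing_features, 0)
})

test_that("a feature missing on every day is flagged and drops the sample
           from datasets that need its group", {
  w <- mini_world(c(rep(TRUE, 4), rep(FALSE, 4)))
  w$daily$sdnn <- NA_real_
  s <- impute_sample(build_sample("P1", "2023-03-08", 14, w$daily, w$summary))
  expect_equal(s$all_missing_features, "sdnn")

  w2 <- mini_world(rep(TRUE, 8))
  w2$daily$participant_id <- "P2"
  w2$summary$participant_id <- "P2"
  s2 <- impute_sample(build_sample("P2", "2023-03-08", 8, w2$daily, w2$summary))
  ds <- assemble(list(s, s2))
  expect_equal(nrow(ds$hrv$x), 1)          # P1 dropped where HRV required
  expect_equal(nrow(ds$all$x), 1)
  expect_equal(nrow(ds$sleep$x), 2)        # kept where HRV not required
  expect_equal(ds$hrv$dropped, "P1@2023-03-08")
})

test_that("collapse averages days (or concatenates on request)", {
  w <- mini_world(rep(TRUE, 8))
  s <- impute_sample(build_sample("P1", "2023-03-08", 14, w$daily, w$summary))
  v <- collapse_sample(s)
  expect_equal(v[["step_counts"]], 7000)   # mean of 4x8000, 4x6000
  expect_equal(v[["tst"]], 1)              # constant daily values pass through
  vc <- collapse_sample(s, "concat")
  expect_length(vc, 8 * ncol(s$days))
  expect_equal(vc[["step_counts_d1"]], 8000)
})

test_that("assemble produces 7 consistent datasets with the right columns", {
  st <- small_cohort_state()
  ds <- st$datasets
  expect_named(ds, c("sleep", "hrv", "pa", "sleep+hrv", "sleep+pa",
                     "hrv+pa", "all"))
  expect_equal(ncol(ds$hrv$x), 7)
  expect_equal(ncol(ds$sleep$x), 6)
  expect_equal(ncol(ds$pa$x), 28)
  expect_equal(ncol(ds$all$x), 41)
  expect_equal(sort(colnames(ds$all$x)),
               sort(unique(c(colnames(ds$hrv$x), colnames(ds$sleep$x),
                             colnames(ds$pa$x)))))
  ids <- lapply(ds, `[[`, "sample_id")
  for (i in 2:7) expect_identical(ids[[i]], ids[[1]])
  ys <- lapply(ds, `[[`, "y")
  for (i in 2:7) expect_identical(ys[[i]], ys[[1]])
  expect_error(assemble(list()), "no retained samples")
})
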