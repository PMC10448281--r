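test_that("compute_metrics matches confusion-matrix arithmetic", {
  # TP=15 FN=2 TN=19 FP=3
  truth <- c(rep(1, 17), rep(0, 22))
  pred <- c(rep(1, 15), rep(0, 2), rep(0, 19), rep(1, 3))
  m <- compute_metrics(truth, pred)
  expect_equal(m$sensitivity, 15 / 17)
  expect_equal(m$specificity, 19 / 22)
  expect_equal(m$precision_loneliness, 15 / 18)
  expect_equal(m$precision_nonlonely, 19 / 21)
  expect_equal(m$recall_loneliness, 15 / 17)
  expect_equal(m$recall_nonlonely, 19 / 22)
  f1_1 <- 2 * (15 / 18) * (15 / 17) / (15 / 18 + 15 / 17)
  f1_0 <- 2 * (19 / 21) * (19 / 22) / (19 / 21 + 19 / 22)
  expect_equal(m$f1_loneliness, f1_1)
  expect_equal(m$f1_nonlonely, f1_0)
  expect_equal(m$weighted_f1, (22 * f1_0 + 17 * f1_1) / 39)

  perfect <- compute_metrics(truth, truth, scores = truth)
  for (k in c("precision_nonlonely", "precision_loneliness", "weighted_f1",
              "sensitivity", "specificity", "auc"))
    expect_equal(perfect[[k]], 1)

  all_pos <- compute_metrics(truth, rep(1, 39))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)

  expect_error(compute_metrics(rep(1, 5), rep(1, 5)), "one class")
})

test_that("AUC equals the Mann-Whitney statistic on random scores", {
  set.seed(51)
  for (i in 1:20) {
    truth <- rbinom(30, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(30)
    m <- compute_metrics(truth, as.integer(scores > 0), scores)
    pairs <- expand.grid(p = scores[truth == 1], n = scores[truth == 0])
    want <- mean(pairs$p > pairs$n) + 0.5 * mean(pairs$p == pairs$n)
    expect_equal(m$auc, want, tolerance = 1e-12)
  }
})

test_that("rfe eliminates the noise column before the separating one", {
  set.seed(52)
  n <- 60
  x <- cbind(activity_intensity = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
             hourly_steps_sd = rnorm(n),
             sdnn = rnorm(n))
  y <- rep(0:1, each = n / 2)
  keep <- rfe_select(x, y, model_spec("decision_tree"), k = 1)
  expect_true("activity_intensity" %in% keep)
  expect_true("sdnn" %in% keep)          # non-activity columns never dropped
  expect_false("hourly_steps_sd" %in% keep)

  # k >= activity count: identity (with warning above the count)
  expect_equal(rfe_select(x, y, model_spec("decision_tree"), k = 2),
               colnames(x))
  expect_warning(rfe_select(x, y, model_spec("decision_tree"), k = 5),
                 "exceeds")
  # no activity columns at all: identity
  x2 <- cbind(sdnn = rnorm(n), tst = rnorm(n))
  expect_equal(rfe_select(x2, y, model_spec("decision_tree"), k = 1),
               colnames(x2))
})

make_dataset <- function(x, y, pid, name = "pa") {
  structure(list(name = name, x = x, y = y, participant_id = pid,
                 sample_id = paste0(pid, "#", seq_along(y)),
                 feature_names = colnames(x), dropped = character(0)),
            class = "lw_dataset")
}

test_that("lopo folds are disjoint by participant and cover every sample", {
  st <- small_cohort_state()
  ds <- st$datasets$pa
  rep <- lopo_evaluate(ds, model_spec("decision_tree"), rfe_k = 10)
  expect_equal(rep$n_folds, length(unique(ds$participant_id)))
  # each sample predicted exactly once
  expect_setequal(rep$predictions$sample_id, ds$sample_id)
  expect_equal(anyDuplicated(rep$predictions$sample_id), 0)
  # multi-sample participants are held out together: the fold id of each
  # sample equals its participant, so both samples share a fold by design
  expect_equal(rep$predictions$participant_id,
               ds$participant_id[match(rep$predictions$sample_id,
                                       ds$sample_id)])
})

test_that("perfectly separable synthetic dataset scores weighted F1 of 1", {
  set.seed(53)
  n <- 24
  x <- cbind(activity_intensity = c(rnorm(n / 2, 0), rnorm(n / 2, 8)),
             noise = rnorm(n))
  y <- rep(0:1, each = n / 2)
  pid <- paste0("P", rep(1:12, each = 2))
  ds <- make_dataset(x, y, pid)
  for (kind in c("decision_tree", "gradient_boosting")) {
    rep <- lopo_evaluate(ds, model_spec(kind), rfe_k = 1)
    expect_equal(rep$metrics$weighted_f1, 1)
  }
})

test_that("metric identities hold on a real evaluation report", {
  st <- small_cohort_state()
  rep <- lopo_evaluate(st$datasets$pa, model_spec("gradient_boosting"),
                       rfe_k = 10)
  m <- rep$metrics
  cm <- m$confusion
  expect_equal(m$sensitivity, m$recall_loneliness, tolerance = 1e-9)
  expect_equal(m$specificity, m$recall_nonlonely, tolerance = 1e-9)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  p1 <- cm[["tp"]] / (cm[["tp"]] + cm[["fp"]])
  r1 <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  p0 <- cm[["tn"]] / (cm[["tn"]] + cm[["fn"]])
  r0 <- cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
  n1 <- cm[["tp"]] + cm[["fn"]]; n0 <- cm[["tn"]] + cm[["fp"]]
  expect_equal(m$weighted_f1,
               (n0 * f1(p0, r0) + n1 * f1(p1, r1)) / (n0 + n1),
               tolerance = 1e-9)
  expect_true(all(unlist(m[setdiff(names(m), "confusion")]) >= 0 &
                    unlist(m[setdiff(names(m), "confusion")]) <= 1))
})

test_that("one-class training folds are skipped with a warning", {
  set.seed(54)
  x <- cbind(a = rnorm(6), b = rnorm(6))
  y <- c(1, 0, 0, 0, 0, 0)      # removing P1 leaves one class
  pid <- paste0("P", 1:6)
  ds <- make_dataset(x, y, pid)
  expect_warning(rep <- lopo_evaluate(ds, model_spec("decision_tree"),
                                      rfe_k = NULL),
                 "one-class")
  expect_equal(rep$skipped_folds, "P1")
  # with the only positive participant skipped, pooled metrics are undefined
  expect_null(rep$metrics)
})

test_that("evaluate_all returns the 10-column metric table for 7 datasets", {
  st <- small_cohort_state()
  res <- evaluate_all(st$datasets,
                      specs = list(model_spec("decision_tree")), rfe_k = 10)
  expect_equal(nrow(res$table), 7)
  expect_equal(ncol(res$table), 12)  # model + dataset + 10 measures
  expect_true(all(res$table$weighted_f1 >= 0 & res$table$weighted_f1 <= 1))
})
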