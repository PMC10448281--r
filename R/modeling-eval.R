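#' Classification metrics from pooled predictions
#'
#' Per-class precision, recall and F1 for the nonlonely (0) and
#' loneliness (1) classes, the support-weighted F1, sensitivity (recall
#' of the loneliness class), specificity (recall of the nonlonely
#' class), and AUC computed from the scores by the rank (Mann-Whitney)
#' statistic. Precision of a class nobody was assigned to is defined
#' as 0.
#'
#' @param truth true 0/1 labels (both classes must be present).
#' @param pred predicted 0/1 labels.
#' @param scores class-1 probabilities (for AUC); optional.
#' @return named list of metrics, all in `[0, 1]`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(unique(truth)) < 2)
    stop("metrics undefined: only one class present in truth")
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  prec <- function(tp, fp) if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  p1 <- prec(tp, fp); r1 <- tp / (tp + fn)
  p0 <- prec(tn, fn); r0 <- tn / (tn + fp)
  f11 <- f1(p1, r1); f10 <- f1(p0, r0)
  n0 <- tn + fp; n1 <- tp + fn
  auc <- NA_real_
  if (!is.null(scores)) {
    rk <- rank(scores)
    auc <- (sum(rk[truth == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }
  list(precision_nonlonely = p0, precision_loneliness = p1,
       recall_nonlonely = r0, recall_loneliness = r1,
       f1_nonlonely = f10, f1_loneliness = f11,
       weighted_f1 = (n0 * f10 + n1 * f11) / (n0 + n1),
       sensitivity = r1, specificity = r0, auc = auc,
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Recursive feature elimination over activity features
#'
#' Repeatedly fits the estimator and removes the least important
#' physical-activity feature until `k` activity features remain.
#' Non-activity columns are never candidates for elimination. Intended
#' to run inside each cross-validation training fold.
#'
#' @param x training feature matrix.
#' @param y training labels.
#' @param spec an [model_spec()].
#' @param k activity features to retain.
#' @param activity_cols names of the activity columns in `x`; default:
#'   every column belonging to the activity feature group.
#' @return character vector of retained column names (original order).
#' @export
rfe_select <- function(x, y, spec, k = 10L, activity_cols = NULL) {
  cols <- colnames(x)
  if (is.null(activity_cols)) {
    pa <- feature_groups()$pa
    activity_cols <- cols[sub("_d[1-8]$", "", cols) %in% pa]
  }
  act <- intersect(cols, activity_cols)
  if (!length(act)) return(cols)
  if (k >= length(act)) {
    if (k > length(act))
      warning("k exceeds the number of activity features; nothing eliminated")
    return(cols)
  }
  keep <- cols
  act_left <- act
  while (length(act_left) > k) {
    fit <- fit_model(spec, x[, keep, drop = FALSE], y)
    imp <- fit$importance[act_left]
    drop_col <- act_left[which.min(imp)]
    act_left <- setdiff(act_left, drop_col)
    keep <- setdiff(keep, drop_col)
  }
  keep
}

#' Leave-one-participant-out evaluation
#'
#' One fold per distinct participant: all of a participant's samples are
#' held out together, RFE (activity features only) and model fitting
#' happen strictly inside the training partition, and the out-of-fold
#' predictions are pooled before metrics are computed. Folds whose
#' training partition contains a single class are skipped with a
#' warning and recorded.
#'
#' @param dataset an `lw_dataset` from [assemble()].
#' @param spec an [model_spec()].
#' @param rfe_k activity features to retain per fold (`NULL` or `Inf`
#'   disables RFE).
#' @param threshold probability threshold for the positive class.
#' @return an `lw_eval_report`: pooled `metrics`, `predictions`
#'   data.frame, mean `importance` across folds (descending), per-fold
#'   `selected_features`, `skipped_folds`, and `fold_accuracy_mean`.
#' @export
lopo_evaluate <- function(dataset, spec, rfe_k = 10L, threshold = 0.5) {
  stopifnot(inherits(dataset, "lw_dataset"))
  x <- dataset$x; y <- dataset$y; pid <- dataset$participant_id
  participants <- unique(pid)
  if (length(participants) < 2) stop("need at least 2 participants")
  preds <- data.frame()
  skipped <- character(0)
  selected <- list()
  imp_sum <- stats::setNames(numeric(ncol(x)), colnames(x))
  n_fit <- 0L
  fold_acc <- c()
  for (p in participants) {
    test <- pid == p
    ytr <- y[!test]
    if (length(unique(ytr)) < 2) {
      warning("fold for participant ", p, " skipped: one-class training set")
      skipped <- c(skipped, p)
      next
    }
    keep <- colnames(x)
    if (!is.null(rfe_k) && is.finite(rfe_k)) {
      keep <- rfe_select(x[!test, , drop = FALSE], ytr, spec, k = rfe_k)
    }
    fit <- fit_model(spec, x[!test, keep, drop = FALSE], ytr)
    score <- predict(fit, x[test, keep, drop = FALSE])
    preds <- rbind(preds, data.frame(
      sample_id = dataset$sample_id[test], participant_id = p,
      truth = y[test], score = score,
      pred = as.integer(score >= threshold)))
    imp_sum[keep] <- imp_sum[keep] + fit$importance
    n_fit <- n_fit + 1L
    selected[[p]] <- keep
    fold_acc <- c(fold_acc, mean(as.integer(score >= threshold) == y[test]))
  }
  if (!nrow(preds)) stop("all folds skipped")
  # pooled truth can degenerate to one class when skipped folds held the
  # only members of a class; the report is still returned, metrics NULL
  metrics <- tryCatch(compute_metrics(preds$truth, preds$pred, preds$score),
                      error = function(e) NULL)
  importance <- sort(imp_sum / max(n_fit, 1L), decreasing = TRUE)
  structure(list(dataset = dataset$name, model = spec$kind,
                 metrics = metrics, predictions = preds,
                 importance = importance, selected_features = selected,
                 skipped_folds = skipped,
                 fold_accuracy_mean = mean(fold_acc),
                 n_folds = length(participants) - length(skipped),
                 spec = spec, rfe_k = rfe_k),
            class = "lw_eval_report")
}

#' Ranked feature-importance table of an evaluation report
#'
#' Impurity-decrease importances averaged over the cross-validation
#' folds (features a fold did not select contribute 0 in that fold).
#'
#' @param report an `lw_eval_report`.
#' @return data.frame with columns `feature` and `importance`, sorted
#'   descending.
#' @export
feature_importance <- function(report) {
  stopifnot(inherits(report, "lw_eval_report"))
  data.frame(feature = names(report$importance),
             importance = as.numeric(report$importance),
             row.names = NULL)
}

#' Evaluate both models on every dataset
#'
#' @param datasets list of 7 datasets from [assemble()].
#' @param specs list of [model_spec()]s (default: the decision tree and
#'   gradient boosting at their default hyperparameters).
#' @param rfe_k activity features retained per fold.
#' @return list with `reports` (nested by model then dataset) and
#'   `table`, a data.frame shaped like the usual published summary: one
#'   row per (model, dataset), ten metric columns.
#' @export
evaluate_all <- function(datasets,
                         specs = list(model_spec("decision_tree"),
                                      model_spec("gradient_boosting")),
                         rfe_k = 10L) {
  rows <- list()
  reports <- list()
  for (spec in specs) {
    for (ds in datasets) {
      rep <- lopo_evaluate(ds, spec, rfe_k = rfe_k)
      reports[[spec$kind]][[ds$name]] <- rep
      m <- rep$metrics
      rows[[length(rows) + 1]] <- data.frame(
        model = spec$kind, dataset = ds$name,
        precision_nonlonely = m$precision_nonlonely,
        precision_loneliness = m$precision_loneliness,
        recall_nonlonely = m$recall_nonlonely,
        recall_loneliness = m$recall_loneliness,
        f1_nonlonely = m$f1_nonlonely,
        f1_loneliness = m$f1_loneliness,
        weighted_f1 = m$weighted_f1,
        sensitivity = m$sensitivity, specificity = m$specificity,
        auc = m$auc)
    }
  }
  list(reports = reports, table = do.call(rbind, rows))
}

#' @export
print.lw_eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("LOPO evaluation: %s on '%s' (%d folds%s)\n", x$model,
              x$dataset, x$n_folds,
              if (length(x$skipped_folds))
                paste0(", ", length(x$skipped_folds), " skipped") else ""))
  cat(sprintf("  weighted F1 %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
              m$weighted_f1, m$sensitivity, m$specificity, m$auc))
  top <- utils::head(names(x$importance), 3)
  cat("  top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}
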