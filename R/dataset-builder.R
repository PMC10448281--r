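#' Score a UCLA-12 response
#'
#' The 12-item UCLA loneliness scale has a social and an emotional
#' factor, each covered by 6 items scored 1-4, so each factor score
#' ranges 6-24. The item-to-factor mapping is configurable; the default
#' assigns odd items to the social factor.
#'
#' @param items numeric vector of the 12 item scores.
#' @param social_items indices of the 6 social-factor items.
#' @return named vector `c(social_score, emotional_score)`; `NA`s when
#'   any contributing item is missing.
#' @export
score_ucla <- function(items, social_items = seq(1, 11, 2)) {
  stopifnot(length(items) == 12, length(social_items) == 6)
  s <- sum(items[social_items])
  e <- sum(items[-social_items])
  c(social_score = if (anyNA(items[social_items])) NA_real_ else s,
    emotional_score = if (anyNA(items[-social_items])) NA_real_ else e)
}

#' Binary loneliness label from the UCLA social score
#'
#' Social score of at least 12 is labelled 1 (loneliness), below 12 is 0.
#'
#' @param social_score score in `[6, 24]`.
#' @return integer 0/1.
#' @export
loneliness_label <- function(social_score) {
  if (any(!is.na(social_score) & (social_score < 6 | social_score > 24)))
    stop("social score outside [6, 24]")
  ifelse(is.na(social_score), NA_integer_, as.integer(social_score >= 12))
}

#' Valid-day rule
#'
#' A day is valid when the watch was worn for at least 10 hours
#' (600 minutes) during waking time and collected valid sleep data.
#'
#' @param wear_min_awake awake wear time in minutes (vectorised).
#' @param has_valid_sleep logical.
#' @return logical.
#' @export
is_valid_day <- function(wear_min_awake, has_valid_sleep) {
  wear_min_awake >= 600 & as.logical(has_valid_sleep)
}

#' Build one labeled 8-day data sample
#'
#' Collects the daily feature rows of the 7 days before and the day of a
#' questionnaire response. Days failing the valid-day rule contribute
#' all-missing rows. Samples with fewer than 4 valid days are excluded.
#'
#' @param participant_id participant.
#' @param response_date Date the questionnaire was answered.
#' @param social_score UCLA social factor score.
#' @param daily daily feature table from [extract_daily_features()].
#' @param summary day-summary table (valid-day flags).
#' @return a `data_sample` (list with `days` 8 x features matrix,
#'   `valid_day_count`, `label`), or an `excluded_sample` sentinel whose
#'   `reason` attribute says why.
#' @export
build_sample <- function(participant_id, response_date, social_score,
                         daily, summary) {
  excluded <- function(reason)
    structure(list(), class = "excluded_sample", reason = reason)
  if (is.na(social_score)) return(excluded("missing UCLA score"))
  window <- seq(as.Date(response_date) - 7, as.Date(response_date), by = "day")
  feat_names <- unlist(feature_groups(), use.names = FALSE)
  days <- matrix(NA_real_, nrow = 8, ncol = length(feat_names),
                 dimnames = list(as.character(window), feat_names))
  valid <- logical(8)
  for (i in seq_along(window)) {
    s <- summary[summary$participant_id == participant_id &
                   summary$date == window[i], , drop = FALSE]
    valid[i] <- nrow(s) > 0 && isTRUE(s$valid[1])
    if (!valid[i]) next
    d <- daily[daily$participant_id == participant_id &
                 daily$date == window[i], , drop = FALSE]
    if (nrow(d)) days[i, ] <- unlist(d[1, feat_names])
  }
  if (sum(valid) < 4)
    return(excluded(sprintf("only %d valid days", sum(valid))))
  structure(list(participant_id = participant_id,
                 response_date = as.Date(response_date),
                 days = days, valid_days = valid,
                 valid_day_count = sum(valid),
                 label = loneliness_label(social_score)),
            class = "data_sample")
}

#' Within-sample mean imputation
#'
#' Each missing daily value of a feature is replaced by the mean of that
#' feature's observed values within the same 8-day sample; observed
#' values are untouched. Features missing on all 8 days stay missing and
#' are flagged.
#'
#' @param sample a `data_sample`.
#' @return the sample with `days` imputed and `all_missing_features`
#'   recorded.
#' @export
impute_sample <- function(sample) {
  stopifnot(inherits(sample, "data_sample"))
  d <- sample$days
  all_missing <- character(0)
  for (j in seq_len(ncol(d))) {
    obs <- !is.na(d[, j])
    if (!any(obs)) {
      all_missing <- c(all_missing, colnames(d)[j])
    } else if (!all(obs)) {
      d[!obs, j] <- mean(d[obs, j])
    }
  }
  sample$days <- d
  sample$all_missing_features <- all_missing
  sample
}

#' Collapse an imputed sample to one feature vector
#'
#' The default collapses the 8 daily rows by their per-feature mean;
#' `"concat"` concatenates them into an `8 * f` vector (features suffixed
#' `_d1` ... `_d8`).
#'
#' @param sample an imputed `data_sample`.
#' @param method `"mean"` or `"concat"`.
#' @return named numeric vector.
#' @export
collapse_sample <- function(sample, method = c("mean", "concat")) {
  method <- match.arg(method)
  d <- sample$days
  if (method == "mean") return(colMeans(d))
  v <- as.numeric(t(d))
  stats::setNames(v, as.vector(t(outer(paste0("_d", 1:8), colnames(d),
                                       function(s, f) paste0(f, s)))))
}

#' Build all data samples of a cohort
#'
#' One candidate sample per UCLA response; applies scoring, labeling,
#' the valid-day and >= 4-valid-day rules, and imputation.
#'
#' @param daily,summary tables from [extract_cohort_features()].
#' @param ucla UCLA response table (`participant_id`, `date`,
#'   `item_1` ... `item_12`).
#' @param social_items item-to-factor mapping (see [score_ucla()]).
#' @return list with `samples` (list of imputed `data_sample`s) and
#'   `exclusions` (data.frame of rejected responses with reasons).
#' @export
build_samples <- function(daily, summary, ucla, social_items = seq(1, 11, 2)) {
  samples <- list()
  excl <- data.frame()
  for (i in seq_len(nrow(ucla))) {
    r <- ucla[i, ]
    sc <- score_ucla(as.numeric(r[paste0("item_", 1:12)]), social_items)
    s <- build_sample(r$participant_id, r$date, sc[["social_score"]],
                      daily, summary)
    if (inherits(s, "excluded_sample")) {
      excl <- rbind(excl, data.frame(participant_id = r$participant_id,
                                     date = as.Date(r$date),
                                     reason = attr(s, "reason")))
    } else {
      s$social_score <- sc[["social_score"]]
      s$emotional_score <- sc[["emotional_score"]]  # stored, never a label
      samples[[length(samples) + 1]] <- impute_sample(s)
    }
  }
  list(samples = samples, exclusions = excl)
}

#' Assemble the 7 feature-set datasets
#'
#' The seven non-empty unions of the three feature groups (sleep, HRV,
#' physical activity) become named datasets sharing sample order and
#' labels. A sample whose required feature group contains an
#' all-missing feature is dropped from the datasets needing that group
#' (and logged).
#'
#' @param samples list of imputed `data_sample`s.
#' @param collapse passed to [collapse_sample()].
#' @return named list of 7 `lw_dataset` objects (`name`, `x`, `y`,
#'   `participant_id`, `feature_names`, `dropped`).
#' @export
assemble <- function(samples, collapse = "mean") {
  if (!length(samples)) stop("no retained samples to assemble")
  groups <- feature_groups()
  combos <- list(sleep = "sleep", hrv = "hrv", pa = "pa",
                 `sleep+hrv` = c("sleep", "hrv"),
                 `sleep+pa` = c("sleep", "pa"),
                 `hrv+pa` = c("hrv", "pa"),
                 all = c("hrv", "sleep", "pa"))
  vecs <- lapply(samples, collapse_sample, method = collapse)
  x_all <- do.call(rbind, vecs)
  y <- vapply(samples, `[[`, numeric(1), "label")
  pid <- vapply(samples, `[[`, character(1), "participant_id")
  rdate <- vapply(samples, function(s) as.character(s$response_date), "")
  sample_id <- paste(pid, rdate, sep = "@")

  lapply(stats::setNames(names(combos), names(combos)), function(nm) {
    cols <- unlist(groups[combos[[nm]]], use.names = FALSE)
    sel <- grepl(paste0("^(", paste(cols, collapse = "|"), ")(_d[1-8])?$"),
                 colnames(x_all))
    x <- x_all[, sel, drop = FALSE]
    keep <- stats::complete.cases(x)
    structure(list(name = nm, x = x[keep, , drop = FALSE], y = y[keep],
                   participant_id = pid[keep], sample_id = sample_id[keep],
                   feature_names = colnames(x),
                   dropped = sample_id[!keep]),
              class = "lw_dataset")
  })
}
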