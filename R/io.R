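# CSV schemas shared by the generator (writer) and the pipeline (reader).
# All timestamps are ISO-8601 UTC.

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a synthetic cohort to a directory of CSV files
#'
#' Emits the same schemas the pipeline reads: `sleep.csv`,
#' `activity.csv`, `ucla.csv`, `ibi.csv` (fast mode) or `ppg.csv` (raw
#' waveforms), plus a `ground_truth.json` sidecar with labels and
#' dropped days.
#'
#' @param cohort list of participant bundles.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sleep <- do.call(rbind, lapply(cohort, `[[`, "sleep_nights"))
  sleep$sleep_onset <- .fmt_time(sleep$sleep_onset)
  sleep$sleep_offset <- .fmt_time(sleep$sleep_offset)
  utils::write.csv(sleep, file.path(dir, "sleep.csv"), row.names = FALSE)

  act <- do.call(rbind, lapply(cohort, `[[`, "activity_records"))
  act$interval_start <- .fmt_time(act$interval_start)
  utils::write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE)

  utils::write.csv(do.call(rbind, lapply(cohort, `[[`, "ucla_responses")),
                   file.path(dir, "ucla.csv"), row.names = FALSE)

  ibi <- do.call(rbind, lapply(cohort, function(b) {
    if (!length(b$ibi_windows)) return(NULL)
    do.call(rbind, lapply(b$ibi_windows, function(w) data.frame(
      participant_id = w$participant_id, date = w$date,
      window_start = .fmt_time(w$start_time), interval_ms = w$intervals)))
  }))
  if (!is.null(ibi))
    utils::write.csv(ibi, file.path(dir, "ibi.csv"), row.names = FALSE)

  ppg <- do.call(rbind, lapply(cohort, function(b) {
    if (!length(b$ppg_segments)) return(NULL)
    do.call(rbind, lapply(b$ppg_segments, function(s) data.frame(
      participant_id = s$participant_id,
      timestamp_iso8601 = .fmt_time(s$start_time +
                                      (seq_along(s$samples) - 1) / s$fs_hz),
      amplitude = s$samples)))
  }))
  if (!is.null(ppg))
    utils::write.csv(ppg, file.path(dir, "ppg.csv"), row.names = FALSE)

  gt <- lapply(cohort, function(b) list(
    participant_id = b$participant_id, label = b$true_label,
    dropped_days = as.character(b$ground_truth$dropped_days),
    days = b$ground_truth$days))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort directory back into participant bundles
#'
#' Inverse of [write_cohort()] for the streams the pipeline consumes.
#' PPG segment boundaries are inferred from gaps of at least 60 s in the
#' per-participant timestamp sequence.
#'
#' @param dir directory written by [write_cohort()] (or hand-built with
#'   the same schemas).
#' @return list of participant bundles.
#' @export
read_cohort <- function(dir) {
  sleep <- utils::read.csv(file.path(dir, "sleep.csv"))
  sleep$date <- as.Date(sleep$date)
  sleep$sleep_onset <- .parse_time(sleep$sleep_onset)
  sleep$sleep_offset <- .parse_time(sleep$sleep_offset)
  act <- utils::read.csv(file.path(dir, "activity.csv"))
  act$interval_start <- .parse_time(act$interval_start)
  ucla <- utils::read.csv(file.path(dir, "ucla.csv"))
  ucla$date <- as.Date(ucla$date)

  ibi <- ppg <- NULL
  if (file.exists(file.path(dir, "ibi.csv")))
    ibi <- utils::read.csv(file.path(dir, "ibi.csv"))
  if (file.exists(file.path(dir, "ppg.csv"))) {
    ppg <- utils::read.csv(file.path(dir, "ppg.csv"))
    ppg$timestamp <- .parse_time(ppg$timestamp_iso8601)
  }

  lapply(unique(sleep$participant_id), function(id) {
    ibw <- list()
    if (!is.null(ibi)) {
      sub <- ibi[ibi$participant_id == id, , drop = FALSE]
      for (ws in unique(sub$window_start)) {
        w <- sub[sub$window_start == ws, , drop = FALSE]
        ibw[[length(ibw) + 1]] <- list(
          participant_id = id, date = as.Date(w$date[1]),
          start_time = .parse_time(ws), intervals = w$interval_ms)
      }
    }
    segs <- list()
    if (!is.null(ppg)) {
      sub <- ppg[ppg$participant_id == id, , drop = FALSE]
      sub <- sub[order(sub$timestamp), , drop = FALSE]
      if (nrow(sub)) {
        gap <- c(Inf, diff(as.numeric(sub$timestamp)))
        seg_id <- cumsum(gap >= 60)
        for (g in unique(seg_id)) {
          s <- sub[seg_id == g, , drop = FALSE]
          fs <- 1 / stats::median(diff(as.numeric(s$timestamp)))
          segs[[length(segs) + 1]] <-
            ppg_segment(id, s$timestamp[1], round(fs, 3), s$amplitude)
        }
      }
    }
    structure(list(participant_id = id, true_label = NA_integer_,
                   ppg_segments = segs, ibi_windows = ibw,
                   sleep_nights = sleep[sleep$participant_id == id, ,
                                        drop = FALSE],
                   activity_records = act[act$participant_id == id, ,
                                          drop = FALSE],
                   ucla_responses = ucla[ucla$participant_id == id, ,
                                         drop = FALSE],
                   ground_truth = NULL),
              class = "participant_bundle")
  })
}

#' Write the per-dataset CSVs and an evaluation report
#'
#' @param datasets list from [assemble()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_datasets <- function(datasets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in datasets) {
    df <- as.data.frame(ds$x)
    df$label <- ds$y
    utils::write.csv(cbind(data.frame(sample_id = ds$sample_id,
                                      participant_id = ds$participant_id), df),
                     file.path(dir, paste0("dataset_",
                                           gsub("\\+", "_", ds$name), ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset CSV written by [write_datasets()]
#'
#' @param path CSV path.
#' @param name dataset name to record.
#' @return an `lw_dataset`.
#' @export
read_dataset <- function(path, name = sub("^dataset_", "",
                                          sub("\\.csv$", "", basename(path)))) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, setdiff(colnames(df),
                              c("sample_id", "participant_id", "label")),
                    drop = FALSE])
  structure(list(name = name, x = x, y = df$label,
                 participant_id = df$participant_id,
                 sample_id = df$sample_id, feature_names = colnames(x),
                 dropped = character(0)),
            class = "lw_dataset")
}
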