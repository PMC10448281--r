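#' Sleep quality indicator
#'
#' A night has good sleep quality when wake after sleep onset (WASO) is
#' at most 20 minutes.
#'
#' @param waso minutes awake after sleep onset (vectorised).
#' @return logical; `NA` where `waso` is missing.
#' @export
sleep_quality_indicator <- function(waso) {
  ifelse(is.na(waso), NA, waso <= 20)
}

#' Sufficient sleep indicator
#'
#' Total sleep time between 7 and 8.5 hours (closed interval,
#' 420-510 minutes) counts as sufficient.
#'
#' @param tst total sleep time in minutes (vectorised).
#' @return logical; `NA` where `tst` is missing.
#' @export
sufficient_sleep <- function(tst) {
  ifelse(is.na(tst), NA, tst >= 420 & tst <= 510)
}

#' Nightly sleep feature row
#'
#' Passes the watch-provided summaries through unchanged and appends the
#' two threshold indicators. Invalid nights yield an all-missing row.
#'
#' @param night one-row data.frame (or list) with `tst_min`,
#'   `fragmentation`, `waso_min`, `avg_hand_movement`, `valid`.
#' @return named numeric vector of the six sleep features (indicators
#'   coded 0/1).
#' @export
derive_sleep_row <- function(night) {
  out <- c(tst = NA_real_, fragmentation = NA_real_, waso = NA_real_,
           avg_hand_movement = NA_real_, sleep_quality_indicator = NA_real_,
           sufficient_sleep = NA_real_)
  if (is.null(night) || !isTRUE(as.logical(night$valid))) return(out)
  c(tst = as.numeric(night$tst_min),
    fragmentation = as.numeric(night$fragmentation),
    waso = as.numeric(night$waso_min),
    avg_hand_movement = as.numeric(night$avg_hand_movement),
    sleep_quality_indicator = as.numeric(sleep_quality_indicator(night$waso_min)),
    sufficient_sleep = as.numeric(sufficient_sleep(night$tst_min)))
}

#' Fallback validity rule for a sleep night
#'
#' The watch flags valid nights itself; when the flag is absent a night
#' counts as valid if it recorded positive sleep with a well-formed
#' interval.
#'
#' @param night list/row with `tst_min`, `sleep_onset`, `sleep_offset`
#'   and optionally `valid`.
#' @return logical.
#' @export
sleep_night_valid <- function(night) {
  if (!is.null(night$valid) && !is.na(night$valid)) return(as.logical(night$valid))
  !is.na(night$tst_min) && night$tst_min > 0 &&
    !is.na(night$sleep_onset) && !is.na(night$sleep_offset) &&
    night$sleep_offset > night$sleep_onset
}
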