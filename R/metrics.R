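#' Epoch-level confusion counts
#'
#' @param truth Integer 0/1 reference labels per epoch.
#' @param estimate Integer 0/1 decisions per epoch.
#' @return One-row tibble with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("truth and estimate must have equal length")
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    abort("truth and estimate must be binary 0/1")
  }
  tibble(
    tp = sum(truth == 1 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1)
  )
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(sensitivity * specificity)`, on the percent scale: the class-balance
#' robust summary used for epoch-level evaluation (e.g. sensitivity 52 and
#' specificity 96.78 give a G-mean of 70.94).
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`.
#' @return Percentage in `[0, 100]`.
#' @export
g_mean <- function(sensitivity, specificity) {
  sqrt(sensitivity * specificity)
}

#' Epoch-based evaluation metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and their G-mean, all as percentages at full internal
#' precision (round only for presentation).
#'
#' @param truth Integer 0/1 labels per epoch (or a one-row counts tibble from
#'   [confusion_counts()] if `estimate` is missing).
#' @param estimate Integer 0/1 decisions per epoch.
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `g_mean` (percent) and the four counts.
#' @export
epoch_metrics <- function(truth, estimate = NULL) {
  counts <- if (is.null(estimate)) as_tibble(truth) else confusion_counts(truth, estimate)
  stopifnot(all(c("tp", "fn", "tn", "fp") %in% names(counts)))
  if (counts$tp + counts$fn == 0) abort("no seizure epochs in the reference: sensitivity undefined")
  if (counts$tn + counts$fp == 0) abort("no nonseizure epochs in the reference: specificity undefined")
  sens <- 100 * counts$tp / (counts$tp + counts$fn)
  spec <- 100 * counts$tn / (counts$tn + counts$fp)
  acc <- 100 * (counts$tp + counts$tn) / (counts$tp + counts$fn + counts$tn + counts$fp)
  dplyr::bind_cols(
    tibble(
      sensitivity = sens, specificity = spec, accuracy = acc,
      g_mean = g_mean(sens, spec)
    ),
    counts
  )
}

#' Turn an epoch decision series into seizure events
#'
#' Each maximal run of positive epochs becomes one event spanning from the
#' first epoch's start to the last epoch's end (half-open seconds).
#'
#' @param decisions Integer 0/1 vector, or a data frame with `decision` and
#'   `start_s` columns (e.g. from [run_detector()]).
#' @param epoch_len_s Epoch length in seconds.
#' @param start_s Optional epoch start times; defaults to
#'   `0, epoch_len_s, 2 * epoch_len_s, ...`
#' @return Tibble of events with `start_s`, `end_s`.
#' @examples
#' extract_events(c(0, 1, 1, 0, 1), epoch_len_s = 4) # (4,12) and (16,20)
#' @export
extract_events <- function(decisions, epoch_len_s = 4, start_s = NULL) {
  if (is.data.frame(decisions)) {
    start_s <- start_s %||% decisions$start_s
    if ("epoch_len_s" %in% names(decisions)) epoch_len_s <- decisions$epoch_len_s[1]
    decisions <- decisions$decision
  }
  start_s <- start_s %||% ((seq_along(decisions) - 1) * epoch_len_s)
  r <- rle(as.integer(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  ev_start <- start_s[starts[keep]]
  ev_end <- start_s[ends[keep]] + epoch_len_s
  tibble(start_s = ev_start, end_s = ev_end)
}

intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(a_start, b_start) < pmin(a_end, b_end)
}

#' Event-based evaluation metrics
#'
#' A reference event counts as detected when at least one detected event
#' overlaps it by a positive duration (each reference counted once, however
#' many detections hit it); a detected event overlapping no reference is one
#' false positive. The false-detection rate is false positives per evaluated
#' hour.
#'
#' @param detected Tibble of detected events (`start_s`, `end_s`).
#' @param reference Tibble of expert-marked events (`start_s`, `end_s`).
#' @param hours_evaluated Evaluated recording duration in hours (> 0).
#' @return One-row tibble with `n_reference`, `n_detected_true`,
#'   `event_sensitivity` (percent), `n_false_positives`, `fdr_per_hour`,
#'   `hours_evaluated`.
#' @export
event_metrics <- function(detected, reference, hours_evaluated) {
  if (hours_evaluated <= 0) abort("hours_evaluated must be > 0")
  n_ref <- nrow(reference)
  hit_ref <- vapply(seq_len(n_ref), function(i) {
    any(intervals_overlap(
      detected$start_s, detected$end_s,
      reference$start_s[i], reference$end_s[i]
    ))
  }, logical(1))
  fp <- vapply(seq_len(nrow(detected)), function(j) {
    !any(intervals_overlap(
      detected$start_s[j], detected$end_s[j],
      reference$start_s, reference$end_s
    ))
  }, logical(1))
  n_true <- sum(hit_ref)
  tibble(
    n_reference = n_ref,
    n_detected_true = n_true,
    event_sensitivity = if (n_ref > 0) 100 * n_true / n_ref else NA_real_,
    n_false_positives = sum(fp),
    fdr_per_hour = sum(fp) / hours_evaluated,
    hours_evaluated = hours_evaluated
  )
}
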