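#' Detector configuration
#'
#' Bundles every tunable parameter of the pipeline: epoching, VMD, mode
#' screening, deep forest, and postprocessing. Defaults are the detector's
#' standard operating point: 4-s epochs, K = 5 modes with a 0.3 correlation
#' screen, scanning windows 5 and 3, 120 trees per forest, and smoothing
#' windows capped at 35 epochs.
#'
#' @param epoch_len_s Epoch length in seconds.
#' @param K,alpha,tau,tol,max_iter VMD parameters ([vmd()]).
#' @param cor_threshold Mode-screening correlation threshold.
#' @param windows,trees,scan_trees,cv_folds,max_levels,patience Deep-forest
#'   parameters ([fit_deep_forest()]).
#' @param max_window Largest smoothing window ([tune_postprocess()]).
#' @param collar_epochs Collar width; `NULL` (default) uses the tuned
#'   smoothing half-width `M`.
#' @param seed Integer seed for all randomness.
#' @return A list of class `seizure_config`.
#' @export
seizure_config <- function(epoch_len_s = 4, K = 5, alpha = 2000, tau = 0,
                           tol = 1e-7, max_iter = 500, cor_threshold = 0.3,
                           windows = c(5, 3), trees = 120, scan_trees = trees,
                           cv_folds = 3, max_levels = 20, patience = 1,
                           max_window = 35, collar_epochs = NULL, seed = 1) {
  structure(
    list(
      epoch_len_s = epoch_len_s, K = K, alpha = alpha, tau = tau, tol = tol,
      max_iter = max_iter, cor_threshold = cor_threshold, windows = windows,
      trees = trees, scan_trees = scan_trees, cv_folds = cv_folds,
      max_levels = max_levels, patience = patience, max_window = max_window,
      collar_epochs = collar_epochs, seed = as.integer(seed)
    ),
    class = "seizure_config"
  )
}

#' Train the seizure detector on an annotated record
#'
#' Runs the full training protocol: segment the record into epochs and label
#' them from the annotations; decompose every epoch with VMD and fix the
#' retained-mode set by correlation screening on these training epochs;
#' compute LECM features; fit the deep forest on a class-balanced epoch
#' subsample (all seizure epochs plus an equal seeded draw of background
#' epochs); then tune the smoothing window and decision threshold on the full
#' time-ordered training margin series.
#'
#' @param record An annotated [eeg_record()].
#' @param config A [seizure_config()].
#' @param annotations Optional annotations tibble; defaults to the record's.
#' @return An object of class `seizure_detector`: list with the fitted
#'   `model` ([fit_deep_forest()]), tuned `params`
#'   ([tune_postprocess()]), `selected_modes`, `mode_correlations`, `config`,
#'   and the training record's `fs`/`n_channels`.
#' @export
train_detector <- function(record, config = seizure_config(), annotations = NULL) {
  ann <- annotations %||% annotations(record)
  if (is.null(ann) || nrow(ann) == 0) abort("training needs annotated seizure intervals")
  epochs <- label_epochs(segment_epochs(record, config$epoch_len_s), ann)
  if (length(unique(epochs$label)) < 2) {
    abort("training record must contain both seizure and nonseizure epochs")
  }
  feats <- lecm_features(epochs,
    K = config$K, alpha = config$alpha, tau = config$tau, tol = config$tol,
    max_iter = config$max_iter, cor_threshold = config$cor_threshold
  )
  pos <- which(feats$label == 1)
  neg <- which(feats$label == 0)
  n_bal <- min(length(pos), length(neg))
  keep <- sort(c(
    withr::with_seed(config$seed, sample(pos, n_bal)),
    withr::with_seed(config$seed + 1L, sample(neg, n_bal))
  ))
  # scanning windows may not exceed the feature dimension; drop the ones
  # that do (falling back to a single full-width window if none fit)
  d <- length(feature_columns(feats))
  windows <- config$windows[config$windows <= d]
  if (length(windows) == 0) windows <- d
  model <- fit_deep_forest(feats[keep, ],
    windows = windows, trees = config$trees,
    scan_trees = config$scan_trees, cv_folds = config$cv_folds,
    max_levels = config$max_levels, patience = config$patience,
    seed = config$seed
  )
  margin <- prob_margin(predict(model, feats))
  params <- tune_postprocess(margin, feats$label, max_window = config$max_window)
  if (!is.null(config$collar_epochs)) params$collar_epochs <- as.integer(config$collar_epochs)
  structure(
    list(
      model = model, params = params,
      selected_modes = attr(feats, "selected_modes"),
      mode_correlations = attr(feats, "mode_correlations"),
      config = config, fs = eeg_fs(record),
      n_channels = length(eeg_channels(record))
    ),
    class = "seizure_detector"
  )
}

#' @export
print.seizure_detector <- function(x, ...) {
  cat(sprintf(
    "<seizure_detector: %d channel(s) @ %g Hz; modes kept: %s>\n",
    x$n_channels, x$fs, paste(x$selected_modes, collapse = ", ")
  ))
  print(x$model)
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.seizure_detector <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      fs = x$fs, n_channels = x$n_channels,
      selected_modes = paste(x$selected_modes, collapse = ","),
      smoothing_window = x$params$window,
      threshold = x$params$threshold,
      collar_epochs = x$params$collar_epochs
    ),
    glance(x$model)
  )
}

#' Run a trained detector over a record
#'
#' Segments the record, extracts LECM features with the training-time mode
#' selection, predicts per-epoch seizure probabilities, and applies the
#' postprocessing chain. Every intermediate stage is returned so the
#' margin/smoothed/thresholded/collared series can be inspected or plotted.
#'
#' @param record An [eeg_record()] with the sampling rate and channel count
#'   the detector was trained on.
#' @param detector A `seizure_detector` from [train_detector()].
#' @return A tibble of class `seizure_detection` with one row per epoch:
#'   `epoch`, `start_s`, `epoch_len_s`, `p_seizure`, `margin`, `smoothed`,
#'   `decision_raw`, `decision`.
#' @export
run_detector <- function(record, detector) {
  if (abs(eeg_fs(record) - detector$fs) > 1e-9) {
    abort(sprintf(
      "record sampling rate %g Hz does not match the training rate %g Hz",
      eeg_fs(record), detector$fs
    ))
  }
  if (length(eeg_channels(record)) != detector$n_channels) {
    abort(sprintf(
      "record has %d channel(s); the detector was trained on %d",
      length(eeg_channels(record)), detector$n_channels
    ))
  }
  cfg <- detector$config
  epochs <- segment_epochs(record, cfg$epoch_len_s)
  feats <- lecm_features(epochs,
    K = cfg$K, alpha = cfg$alpha, tau = cfg$tau, tol = cfg$tol,
    max_iter = cfg$max_iter, selected_modes = detector$selected_modes
  )
  probs <- predict(detector$model, feats)
  stages <- postprocess(prob_margin(probs), detector$params)
  out <- dplyr::bind_cols(
    epochs[, c("epoch", "start_s", "epoch_len_s")],
    tibble(p_seizure = probs$p_seizure),
    stages
  )
  structure(out,
    params = detector$params,
    class = c("seizure_detection", class(out))
  )
}

#' Detected seizure events of a detection run
#'
#' @param detection A `seizure_detection` tibble from [run_detector()].
#' @return Tibble of events (`start_s`, `end_s`), from [extract_events()].
#' @export
detect_events <- function(detection) {
  extract_events(detection)
}

#' Evaluate a detection run against expert annotations
#'
#' Labels the evaluated epochs from the annotations (any positive overlap =
#' seizure), computes the epoch-based metrics, extracts detected events, and
#' computes the event-based metrics.
#'
#' @param detection A `seizure_detection` tibble from [run_detector()].
#' @param annotations Tibble of reference intervals (`start_s`, `end_s`), or
#'   an annotated `eeg_record`.
#' @param hours_evaluated Hours of data evaluated; defaults to the detection
#'   series' total span.
#' @return One-row tibble combining [epoch_metrics()] and [event_metrics()].
#' @export
evaluate_run <- function(detection, annotations, hours_evaluated = NULL) {
  if (inherits(annotations, "eeg_record")) annotations <- annotations(annotations)
  len <- detection$epoch_len_s[1]
  truth <- as.integer(interval_overlap_s(detection$start_s, len, annotations) > 0)
  hours_evaluated <- hours_evaluated %||% (nrow(detection) * len / 3600)
  dplyr::bind_cols(
    epoch_metrics(truth, detection$decision),
    event_metrics(
      extract_events(detection),
      annotations[, c("start_s", "end_s")],
      hours_evaluated
    )
  )
}
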