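# Independent brute-force oracles used by the metrics and acceptance tests.

oracle_epoch_metrics <- function(truth, est) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && est[i] == 1) {
      tp <- tp + 1L
    } else if (truth[i] == 1) {
      fn <- fn + 1L
    } else if (est[i] == 1) {
      fp <- fp + 1L
    } else {
      tn <- tn + 1L
    }
  }
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  c(
    sensitivity = sens, specificity = spec,
    accuracy = 100 * (tp + tn) / length(truth),
    g_mean = sqrt(sens * spec)
  )
}

oracle_event_metrics <- function(det, ref, hours) {
  hit <- 0L
  for (i in seq_len(nrow(ref))) {
    found <- FALSE
    for (j in seq_len(nrow(det))) {
      if (max(det$start_s[j], ref$start_s[i]) < min(det$end_s[j], ref$end_s[i])) found <- TRUE
    }
    if (found) hit <- hit + 1L
  }
  fp <- 0L
  for (j in seq_len(nrow(det))) {
    found <- FALSE
    for (i in seq_len(nrow(ref))) {
      if (max(det$start_s[j], ref$start_s[i]) < min(det$end_s[j], ref$end_s[i])) found <- TRUE
    }
    if (!found) fp <- fp + 1L
  }
  c(n_detected_true = hit, n_false_positives = fp, fdr_per_hour = fp / hours)
}

random_intervals <- function(n, span, seed) {
  withr::with_seed(seed, {
    starts <- sort(runif(n, 0, span))
    tibble::tibble(start_s = starts, end_s = starts + runif(n, 1, span / n))
  })
}

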