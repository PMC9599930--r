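#' Probability margin of two-class predictions
#'
#' Collapses the two class probabilities into a single score in `[-1, 1]`:
#' `P(seizure) - P(nonseizure)` (equivalently `2 P(seizure) - 1`), the series
#' that the smoothing and threshold stages operate on.
#'
#' @param probs A tibble/matrix of two-class probabilities with columns
#'   `[nonseizure, seizure]` (as returned by [predict.deep_forest()]); rows
#'   must sum to 1 within `1e-6`.
#' @return Numeric vector of per-epoch margins.
#' @export
prob_margin <- function(probs) {
  p <- as.matrix(probs)
  if (ncol(p) != 2) abort("prob_margin() expects two class-probability columns")
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    abort("probability rows must sum to 1 (within 1e-6)")
  }
  unname(p[, 2] - p[, 1])
}

#' Moving-average filter with truncated boundaries
#'
#' Linear moving average of window length `2M + 1`. Interior points average
#' the full window; points within `M` of either end average only the in-range
#' samples, so the filter is mean-preserving at the boundaries rather than
#' padding with phantom zeros.
#'
#' @param x Numeric series.
#' @param M Half-width; `M = 0` is the identity.
#' @return Smoothed series, same length as `x`.
#' @examples
#' moving_average(c(0, 1, 0), M = 1) # 0.5, 1/3, 0.5
#' @export
moving_average <- function(x, M) {
  if (length(x) == 0) abort("empty series")
  M <- as.integer(M)
  if (M < 0) abort("M must be >= 0")
  if (M == 0) {
    return(x)
  }
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - M, 1L)
  hi <- pmin(seq_len(n) + M, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Threshold a smoothed margin series into binary decisions
#'
#' @param x Smoothed margin series.
#' @param threshold Decision cutoff; a value strictly greater than the
#'   threshold is a seizure decision (ties go to nonseizure, the conservative
#'   class).
#' @return Integer vector of 0/1 decisions.
#' @export
apply_decision <- function(x, threshold) {
  as.integer(x > threshold)
}

#' Extend detected runs by a collar
#'
#' Every maximal run of 1s is widened by `collar_epochs` epochs on each side
#' (clipped to the series; overlapping extensions merge), recovering seizure
#' onset/offset epochs that the smoothing stage blurs below threshold.
#'
#' @param decisions Integer 0/1 decision vector.
#' @param collar_epochs Non-negative extension width in epochs.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' collar_extend(c(0, 0, 1, 0, 0), 1) # 0 1 1 1 0
#' @export
collar_extend <- function(decisions, collar_epochs) {
  collar_epochs <- as.integer(collar_epochs)
  if (collar_epochs < 0) abort("collar_epochs must be >= 0")
  if (collar_epochs == 0 || !any(decisions == 1)) {
    return(as.integer(decisions))
  }
  n <- length(decisions)
  r <- rle(as.integer(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(n)
  for (i in which(r$values == 1L)) {
    out[max(1L, starts[i] - collar_epochs):min(n, ends[i] + collar_epochs)] <- 1L
  }
  out
}

#' Tune smoothing window and threshold on training margins
#'
#' Exhaustive grid search over odd smoothing windows `1, 3, ..., max_window`
#' and a threshold grid (fixed steps `-0.9, -0.8, ..., 0.9` plus margin
#' quantiles), selecting the pair that maximizes the epoch-level G-mean of
#' the smoothed-and-thresholded decisions on the training series. Ties are
#' broken toward the smaller window, then the lower threshold. The collar
#' width defaults to the tuned half-width `M`, since the collar exists to
#' compensate the onset/offset blur that the smoothing itself introduces.
#'
#' @param margin Training margin series (time order).
#' @param labels Integer 0/1 epoch labels; both classes must be present.
#' @param max_window Largest smoothing window considered (odd, default 35).
#' @return An object of class `postprocess_params`: list with `M`, `window`
#'   (`2M + 1`), `threshold`, `collar_epochs` and `g_mean` (training G-mean,
#'   percent).
#' @export
tune_postprocess <- function(margin, labels, max_window = 35) {
  if (length(margin) != length(labels)) abort("margin and labels must have equal length")
  pos <- labels == 1
  if (!any(pos) || all(pos)) abort("tuning needs both classes in `labels`")
  thresholds <- sort(unique(round(c(
    seq(-0.9, 0.9, by = 0.1),
    quantile(margin, probs = seq(0.05, 0.95, by = 0.05), names = FALSE)
  ), 10)))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  best <- list(g = -Inf, M = 0L, thr = thresholds[1])
  for (M in 0:((max_window - 1) %/% 2)) {
    sm <- moving_average(margin, M)
    for (thr in thresholds) {
      dec <- sm > thr
      sens <- sum(dec & pos) / n_pos
      spec <- sum(!dec & !pos) / n_neg
      g <- sqrt(sens * spec)
      if (g > best$g) best <- list(g = g, M = M, thr = thr)
    }
  }
  structure(
    list(
      M = best$M, window = 2L * best$M + 1L, threshold = best$thr,
      collar_epochs = best$M, g_mean = 100 * best$g
    ),
    class = "postprocess_params"
  )
}

#' @export
print.postprocess_params <- function(x, ...) {
  cat(sprintf(
    "<postprocess_params: window = %d (M = %d), threshold = %.4g, collar = %d epoch(s), training G-mean = %.2f%%>\n",
    x$window, x$M, x$threshold, x$collar_epochs, x$g_mean
  ))
  invisible(x)
}

#' Apply the full postprocessing chain to a margin series
#'
#' Smooths the margins with [moving_average()], thresholds them with
#' [apply_decision()], and widens the detections with [collar_extend()].
#'
#' @param margin Numeric margin series.
#' @param params `postprocess_params` from [tune_postprocess()] (or a list
#'   with `M`, `threshold`, `collar_epochs`).
#' @return A tibble with columns `margin`, `smoothed`, `decision_raw`
#'   (thresholded) and `decision` (collared).
#' @export
postprocess <- function(margin, params) {
  sm <- moving_average(margin, params$M)
  raw <- apply_decision(sm, params$threshold)
  tibble(
    margin = margin, smoothed = sm, decision_raw = raw,
    decision = collar_extend(raw, params$collar_epochs)
  )
}
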