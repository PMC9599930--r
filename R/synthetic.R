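#' Describe one synthetic seizure
#'
#' @param onset_s Seizure onset in seconds from record start.
#' @param duration_s Seizure duration in seconds.
#' @param hz Fundamental oscillation frequency, in the 3-5 Hz spike-wave
#'   band typical of rhythmic ictal activity.
#' @param amplitude_ratio Strength of the added rhythmic activity: the added
#'   oscillation's RMS is `(amplitude_ratio - 1)` times the background RMS,
#'   so `1` degenerates to pure background (no seizure signature) and larger
#'   values give progressively more prominent seizures.
#' @param n_harmonics Number of harmonics added above the fundamental (with
#'   `1/h` amplitude decay), giving the sharp spike-wave-like morphology.
#' @return One-row tibble describing the seizure.
#' @export
seizure_spec <- function(onset_s, duration_s, hz = 3.5, amplitude_ratio = 5,
                         n_harmonics = 2) {
  if (hz < 3 || hz > 5) abort("seizure oscillation frequency must lie in [3, 5] Hz")
  if (amplitude_ratio < 1) abort("amplitude_ratio must be >= 1")
  if (duration_s <= 0) abort("duration_s must be > 0")
  tibble(
    onset_s = onset_s, duration_s = duration_s, hz = hz,
    amplitude_ratio = amplitude_ratio, n_harmonics = as.integer(n_harmonics)
  )
}

#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the two regimes the detector must separate:
#' broadband `1/f^beta` background activity, and higher-amplitude rhythmic
#' 3-5 Hz harmonic-rich activity during annotated seizure intervals, with
#' 2-second linear amplitude ramps at onset and offset (seizure evolution is
#' gradual, not a step). White measurement noise is added at `snr_db` below
#' the background power.
#'
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of channels (independent backgrounds; the
#'   seizure oscillation is shared across channels, as in a focal recording).
#' @param duration_s Record duration in seconds.
#' @param background_beta Spectral exponent of the `1/f^beta` background.
#' @param background_scale Background RMS amplitude (microvolt scale).
#' @param snr_db Background-to-white-noise power ratio in dB.
#' @param seizures Tibble of seizures from [seizure_spec()] (zero rows for a
#'   seizure-free record); intervals must be non-overlapping and inside the
#'   record.
#' @param seed Integer seed; identical configurations give identical records.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 256, n_channels = 1, duration_s = 600,
                         background_beta = 1, background_scale = 50,
                         snr_db = 20, seizures = NULL, seed = 1) {
  seizures <- seizures %||% tibble(
    onset_s = numeric(), duration_s = numeric(), hz = numeric(),
    amplitude_ratio = numeric(), n_harmonics = integer()
  )
  seizures <- dplyr::arrange(as_tibble(seizures), .data$onset_s)
  if (nrow(seizures) > 0) {
    ends <- seizures$onset_s + seizures$duration_s
    if (any(seizures$onset_s < 0) || any(ends > duration_s)) {
      abort("seizure intervals must lie inside [0, duration_s]")
    }
    if (nrow(seizures) > 1 && any(seizures$onset_s[-1] < ends[-nrow(seizures)])) {
      abort("seizure intervals must not overlap")
    }
  }
  structure(
    list(
      fs = fs, n_channels = as.integer(n_channels), duration_s = duration_s,
      background_beta = background_beta, background_scale = background_scale,
      snr_db = snr_db, seizures = seizures, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# 1/f^beta noise by spectral shaping of seeded white noise, unit RMS.
colored_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) / n
  f <- pmin(f, 1 - f)
  shape <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

ramp_envelope <- function(t_rel, duration_s, ramp_s = 2) {
  ramp_s <- min(ramp_s, duration_s / 2)
  if (ramp_s <= 0) {
    return(rep(1, length(t_rel)))
  }
  pmin(1, pmin(t_rel / ramp_s, (duration_s - t_rel) / ramp_s))
}

#' Generate a synthetic annotated EEG record
#'
#' @param config A [synth_config()].
#' @return An [eeg_record()] whose annotations are exactly the configured
#'   seizure intervals.
#' @examples
#' cfg <- synth_config(
#'   duration_s = 60,
#'   seizures = seizure_spec(onset_s = 20, duration_s = 20), seed = 7
#' )
#' rec <- generate_record(cfg)
#' annotations(rec)
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  samples <- withr::with_seed(config$seed, {
    out <- matrix(0, n, config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      bg <- config$background_scale * colored_noise(n, config$background_beta)
      noise_sd <- config$background_scale * 10^(-config$snr_db / 20)
      x <- bg + stats::rnorm(n, sd = noise_sd)
      bg_rms <- sqrt(mean(bg^2))
      for (i in seq_len(nrow(config$seizures))) {
        sz <- config$seizures[i, ]
        idx <- which(t >= sz$onset_s & t < sz$onset_s + sz$duration_s)
        if (length(idx) == 0) next
        tt <- t[idx] - sz$onset_s
        h <- seq_len(1 + sz$n_harmonics)
        phases <- stats::runif(length(h), 0, 2 * pi)
        osc <- rowSums(vapply(seq_along(h), function(k) {
          sin(2 * pi * h[k] * sz$hz * tt + phases[k]) / h[k]
        }, numeric(length(idx))))
        target_rms <- (sz$amplitude_ratio - 1) * bg_rms
        if (target_rms > 0 && sd(osc) > 0) {
          osc <- osc / sqrt(mean(osc^2)) * target_rms
          x[idx] <- x[idx] + osc * ramp_envelope(tt, sz$duration_s)
        }
      }
      out[, ch] <- x
    }
    out
  })
  eeg_record(samples,
    fs = config$fs,
    annotations = tibble(
      start_s = config$seizures$onset_s,
      end_s = config$seizures$onset_s + config$seizures$duration_s
    )
  )
}

#' Generate a labeled train/test epoch pair
#'
#' Generates two records, segments and labels their epochs, and balances the
#' training epochs (equal seizure/nonseizure counts by seeded subsampling of
#' the nonseizure majority, emulating the practice of training on the
#' seizures plus an equal amount of background). The test epochs are left
#' imbalanced, as deployment data are.
#'
#' @param config_train,config_test [synth_config()]s for the two records.
#' @param epoch_len_s Epoch length in seconds.
#' @return List with `train` (balanced labeled epoch tibble), `test`
#'   (labeled epoch tibble), and the two generated records `train_record`,
#'   `test_record`.
#' @export
generate_dataset <- function(config_train, config_test, epoch_len_s = 4) {
  rec_tr <- generate_record(config_train)
  rec_te <- generate_record(config_test)
  ep_tr <- label_epochs(segment_epochs(rec_tr, epoch_len_s), annotations(rec_tr))
  ep_te <- label_epochs(segment_epochs(rec_te, epoch_len_s), annotations(rec_te))
  pos <- which(ep_tr$label == 1)
  neg <- which(ep_tr$label == 0)
  if (length(pos) == 0) abort("no seizure epochs in the training record")
  if (length(neg) < length(pos)) abort("not enough nonseizure epochs to balance training data")
  keep_neg <- withr::with_seed(config_train$seed + 1L, sort(sample(neg, length(pos))))
  list(
    train = ep_tr[sort(c(pos, keep_neg)), ],
    test = ep_te,
    train_record = rec_tr,
    test_record = rec_te
  )
}
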