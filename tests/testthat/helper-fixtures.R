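# Shared fixtures, all generated in code under fixed seeds.

two_tone <- function(fs = 256, dur = 4, f1 = 5, f2 = 40) {
  t <- (0:(dur * fs - 1)) / fs
  list(t = t, x = sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t), fs = fs)
}

# Ideal band-pass via spectral masking: the independent oracle for what a
# band-limited mode around f0 should look like.
spectral_mask <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

pink_noise <- function(n, beta = 1, seed = 1) {
  withr::with_seed(seed, {
    W <- fft(rnorm(n))
    f <- c(0, seq_len(n - 1)) / n
    f <- pmin(f, 1 - f)
    x <- Re(fft(W * ifelse(f > 0, f^(-beta / 2), 0), inverse = TRUE)) / n
    x / sd(x)
  })
}

# Two Gaussian classes in the first two of d dimensions, class-1 mean offset
# by `sep` per informative dimension.
blob_data <- function(n = 200, d = 6, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[y == 1, 1:2] <- X[y == 1, 1:2] + sep
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(d))
    df$label <- y
    tibble::as_tibble(df)
  })
}

# Welch-averaged one-sided periodogram over non-overlapping segments.
welch_psd <- function(x, fs, seg_s = 4) {
  nper <- floor(seg_s * fs)
  nseg <- floor(length(x) / nper)
  stopifnot(nseg >= 1)
  nf <- nper %/% 2 + 1
  acc <- numeric(nf)
  for (i in seq_len(nseg)) {
    seg <- x[((i - 1) * nper + 1):(i * nper)]
    seg <- seg - mean(seg)
    acc <- acc + (Mod(fft(seg))^2 / nper)[seq_len(nf)]
  }
  data.frame(freq = (seq_len(nf) - 1) / nper * fs, power = acc / nseg)
}

# Ratio of the spectrum to a smooth log-log power-law trend fitted over
# [f_fit_lo, f_fit_hi]; narrowband activity shows up as ratios well above 1.
psd_trend_ratio <- function(psd, f_lo = 2, f_hi = 45) {
  sel <- psd$freq >= f_lo & psd$freq <= f_hi
  lf <- log(psd$freq[sel])
  fit <- stats::lm(log(psd$power[sel]) ~ lf + I(lf^2))
  data.frame(freq = psd$freq[sel], ratio = psd$power[sel] / exp(stats::fitted(fit)))
}
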