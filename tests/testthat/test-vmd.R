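test_that("a zero signal decomposes into identically zero modes", {
  expect_warning(v <- vmd(rep(0, 512), fs = 256, K = 3), "constant")
  expect_equal(max(abs(v$modes)), 0)
  expect_equal(max(abs(v$residual)), 0)
})

test_that("a constant signal warns and parks everything in one mode", {
  expect_warning(v <- vmd(rep(2.5, 256), fs = 64, K = 3), "constant")
  expect_equal(v$modes[, 1], rep(2.5, 256), tolerance = 1e-10)
  expect_lt(max(abs(v$modes[, 2:3])), 1e-10)
})

test_that("two well-separated tones are recovered as separate narrowband modes", {
  tt <- two_tone()
  v <- vmd(tt$x, fs = tt$fs, K = 2, alpha = 2000)
  expect_equal(v$center_freq_hz, c(5, 40), tolerance = 0.5 / 5)
  expect_lt(abs(v$center_freq_hz[1] - 5), 0.5)
  expect_lt(abs(v$center_freq_hz[2] - 40), 0.5)
  # each mode matches the ideal band-passed tone
  oracle1 <- spectral_mask(tt$x, tt$fs, 3, 7)
  oracle2 <- spectral_mask(tt$x, tt$fs, 38, 42)
  expect_gt(abs(cor(v$modes[, 1], oracle1)), 0.95)
  expect_gt(abs(cor(v$modes[, 2], oracle2)), 0.95)
  # near-exact reconstruction for a band-limited signal
  expect_lte(sqrt(sum(v$residual^2) / sum(tt$x^2)), 0.05)
  # residual is the mode-sum complement by definition
  expect_equal(rowSums(v$modes) + v$residual, tt$x, tolerance = 1e-12)
})

test_that("decomposition is deterministic and center frequencies stay in [0, fs/2]", {
  x <- pink_noise(1024, seed = 3)
  v1 <- vmd(x, fs = 256, K = 5)
  v2 <- vmd(x, fs = 256, K = 5)
  expect_identical(v1$modes, v2$modes)
  expect_identical(v1$center_freq_hz, v2$center_freq_hz)
  expect_true(all(v1$center_freq_hz >= 0 & v1$center_freq_hz <= 128))
  expect_true(!is.unsorted(v1$center_freq_hz)) # sorted output
})

test_that("for 1/f noise the slowest mode carries the most variance", {
  x <- pink_noise(1024, seed = 1)
  v <- vmd(x, fs = 256, K = 5)
  vars <- apply(v$modes, 2, var)
  expect_equal(unname(which.max(vars)), 1L)
})

test_that("non-finite input and undersized signals are rejected", {
  expect_error(vmd(c(1, NA, 3, 4), fs = 4, K = 1), "finite")
  expect_error(vmd(rnorm(5), fs = 10, K = 3), "too short")
})

test_that("the center-frequency scan localizes a pure tone and flags over-decomposition", {
  t <- (0:1023) / 256
  scan1 <- center_frequency_scan(sin(2 * pi * 10 * t), fs = 256, K_range = 1)
  expect_equal(nrow(scan1), 1)
  expect_equal(scan1$center_freq_hz, 10, tolerance = 0.05)

  expect_true(vmdforest:::flag_monotone(c(1, 5, 20)))
  # a rise-then-fall center-frequency sequence is the over-decomposition signature
  expect_false(vmdforest:::flag_monotone(c(0.64, 13.34, 27.96, 46.44, 90.96, 8.88)))

  x <- pink_noise(1024, seed = 2) + sin(2 * pi * 8 * t)
  scan <- center_frequency_scan(x, fs = 256, K_range = 1:3)
  expect_equal(nrow(scan), 6)
  expect_named(scan, c("K", "mode", "center_freq_hz", "monotone"))
  expect_type(scan$monotone, "logical")
})

test_that("mode screening keeps modes with correlation strictly above threshold", {
  # typical screened correlation profiles: modes 4-5 at or below 0.3 are dropped
  expect_equal(vmdforest:::select_by_correlation(c(0.7906, 0.7142, 0.3614, 0.1792, 0.0626), 0.3), 1:3)
  expect_equal(vmdforest:::select_by_correlation(c(0.8598, 0.5298, 0.3105, 0.1813, 0.0773), 0.3), 1:3)
  expect_equal(vmdforest:::select_by_correlation(c(0.5, 0.3, 0.2), 0.3), 1L) # exactly 0.3 is rejected

  # modes identical to the signal all survive
  x <- pink_noise(512, seed = 4)
  expect_equal(correlation_select(cbind(x, x, x), x), 1:3)
  expect_error(correlation_select(cbind(x, x), rep(1, 512)), "zero-variance")
})

test_that("the time-frequency matrix stacks selected modes channel-major", {
  tt <- two_tone(fs = 173.6, dur = 4)
  v <- vmd(tt$x[1:694], fs = 173.6, K = 5)
  tf1 <- build_tf_matrix(v, 1:3)
  expect_equal(dim(tf1), c(694, 3))
  expect_equal(unname(tf1), unname(v$modes[, 1:3]))

  tf3 <- build_tf_matrix(list(v, v, v), 1:3)
  expect_equal(ncol(tf3), 9)
  expect_equal(tf3[, 4:6], tf1)

  expect_error(build_tf_matrix(v, integer(0)), "no modes selected")
  v2 <- vmd(tt$x[1:100], fs = 173.6, K = 5)
  expect_error(build_tf_matrix(list(v, v2), 1:3), "equal epoch length")
  expect_error(build_tf_matrix(v, 1:9), "out of range")
})
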