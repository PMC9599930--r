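test_that("the covariance estimator is the (n-1)-divisor sample covariance plus a tiny ridge", {
  X <- cbind(c(1, 2, 3), c(2, 4, 6))
  C <- spd_cov(X)
  expect_equal(unname(C), matrix(c(1, 2, 2, 4), 2), tolerance = 1e-8)
  # collinear columns: singular before the ridge, SPD after
  expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_error(spd_cov(matrix(1:2, 1)), "at least 2 rows")
})

test_that("the matrix logarithm satisfies the textbook identities", {
  expect_equal(spd_logm(diag(3)), matrix(0, 3, 3))
  expect_equal(spd_logm(diag(c(4, 1))), diag(c(log(4), 0)), tolerance = 1e-12)
  expect_error(spd_logm(diag(c(1, -1))), "positive definite")
  expect_error(spd_logm(matrix(1:6, 2)), "square")
})

random_spd <- function(d, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(d * d), d)
    crossprod(A) + diag(0.1, d)
  })
}

test_that("exp(log(C)) round-trips random SPD matrices to high accuracy", {
  for (seed in 1:25) {
    C <- random_spd(5, seed)
    back <- spd_expm(spd_logm(C))
    expect_lt(norm(back - C, "F") / norm(C, "F"), 1e-8)
  }
})

test_that("the log map is congruence-equivariant and additive under scaling", {
  C <- random_spd(4, 7)
  Q <- qr.Q(qr(withr::with_seed(8, matrix(rnorm(16), 4))))
  lhs <- spd_logm(Q %*% C %*% t(Q))
  rhs <- Q %*% spd_logm(C) %*% t(Q)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # log(sC) = log(C) + log(s) I
  expect_equal(spd_logm(3 * C), spd_logm(C) + diag(log(3), 4), tolerance = 1e-8)
})

test_that("half-vectorization walks the upper triangle column-wise", {
  S <- matrix(c(11, 12, 13, 12, 22, 23, 13, 23, 33), 3)
  expect_equal(half_vectorize(S), c(11, 12, 22, 13, 23, 33))
  expect_equal(length(half_vectorize(S)), 6) # d(d+1)/2 for d = 3
  expect_equal(length(half_vectorize(random_spd(9, 1))), 45) # and for d = 9
  expect_equal(half_vectorize(matrix(c(1, 2, 2, 5), 2)), c(1, 2, 5))
  expect_error(half_vectorize(matrix(1:6, 2)), "square")
})

test_that("the feature map yields the expected dimensions for 1 and 3 channels", {
  cfg1 <- synth_config(duration_s = 8, seed = 31)
  ep1 <- segment_epochs(generate_record(cfg1))
  f1 <- lecm_features(ep1, selected_modes = 1:3)
  expect_equal(length(grep("^f[0-9]+$", names(f1))), 6)

  cfg3 <- synth_config(duration_s = 8, n_channels = 3, seed = 32)
  ep3 <- segment_epochs(generate_record(cfg3))
  f3 <- lecm_features(ep3, selected_modes = 1:3)
  expect_equal(length(grep("^f[0-9]+$", names(f3))), 45)
})

test_that("an all-zero epoch cannot be featurized", {
  ep <- segment_epochs(eeg_record(rep(0, 1024), fs = 256))
  expect_error(suppressWarnings(lecm_features(ep)), "zero-variance")
  expect_error(suppressWarnings(lecm_features(ep, selected_modes = 1:3)), "positive definite")
})

test_that("seizure-like epochs shift the diagonal log-covariance entries upward", {
  # one record, rhythmic 3.5 Hz activity over half of it
  cfg <- synth_config(
    duration_s = 480, seed = 41,
    seizures = dplyr::bind_rows(
      seizure_spec(40, 48), seizure_spec(140, 48),
      seizure_spec(240, 48), seizure_spec(340, 48)
    )
  )
  rec <- generate_record(cfg)
  ep <- label_epochs(segment_epochs(rec), annotations(rec))
  feats <- lecm_features(ep, selected_modes = 1:3)
  expect_gte(sum(feats$label == 1), 40)
  expect_gte(sum(feats$label == 0), 60)
  # f1 is logC[1,1], the log-variance of the slowest retained mode
  w <- wilcox.test(feats$f1[feats$label == 1], feats$f1[feats$label == 0],
    alternative = "greater"
  )
  expect_lt(w$p.value, 1e-6)
  expect_gt(
    median(feats$f1[feats$label == 1]),
    median(feats$f1[feats$label == 0])
  )
})
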