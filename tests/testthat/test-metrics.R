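test_that("epoch metrics reproduce hand-worked confusion tables", {
  m <- epoch_metrics(tibble::tibble(tp = 3, fn = 1, tn = 90, fp = 6))
  expect_equal(round(m$sensitivity, 2), 75.00)
  expect_equal(round(m$specificity, 2), 93.75)
  expect_equal(round(m$accuracy, 2), 93.00)
  expect_equal(round(m$g_mean, 2), 83.85)

  perfect <- epoch_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(
    unlist(perfect[c("sensitivity", "specificity", "accuracy", "g_mean")]),
    c(sensitivity = 100, specificity = 100, accuracy = 100, g_mean = 100)
  )

  # a weak-sensitivity patient: G-mean is the geometric mean of the percentages
  expect_equal(round(g_mean(52, 96.78), 2), 70.94)

  expect_error(epoch_metrics(rep(0, 5), rep(0, 5)), "sensitivity undefined")
  expect_error(epoch_metrics(rep(1, 5), rep(1, 5)), "specificity undefined")
})

test_that("epoch metrics agree with the brute-force oracle on random instances", {
  for (seed in 1:200) {
    n <- 5 + seed %% 40
    truth <- withr::with_seed(seed, c(0, 1, rbinom(n, 1, 0.3)))
    est <- withr::with_seed(seed + 1000, rbinom(n + 2, 1, 0.5))
    m <- epoch_metrics(truth, est)
    o <- oracle_epoch_metrics(truth, est)
    expect_equal(
      unlist(m[c("sensitivity", "specificity", "accuracy", "g_mean")]),
      o,
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
})

test_that("decision runs convert to events spanning first start to last end", {
  ev <- extract_events(c(0, 1, 1, 0, 1), epoch_len_s = 4)
  expect_equal(as.data.frame(ev), data.frame(start_s = c(4, 16), end_s = c(12, 20)))
  expect_equal(nrow(extract_events(rep(0, 6))), 0)
  all_on <- extract_events(rep(1, 6), epoch_len_s = 4)
  expect_equal(as.data.frame(all_on), data.frame(start_s = 0, end_s = 24))
})

test_that("event metrics follow the any-overlap matching rule", {
  det <- tibble::tibble(start_s = 10, end_s = 20)
  ref <- tibble::tibble(start_s = c(12, 18), end_s = c(15, 25))
  m <- event_metrics(det, ref, hours_evaluated = 1)
  expect_equal(m$n_detected_true, 2) # one detection can cover two references
  expect_equal(m$n_false_positives, 0)

  none <- event_metrics(det[0, ], ref, hours_evaluated = 2)
  expect_equal(none$event_sensitivity, 0)
  expect_equal(none$n_false_positives, 0)

  # 51 of 54 reference events detected
  ref54 <- tibble::tibble(start_s = (0:53) * 100, end_s = (0:53) * 100 + 50)
  det51 <- ref54[1:51, ]
  m54 <- event_metrics(det51, ref54, hours_evaluated = 10)
  expect_equal(round(m54$event_sensitivity, 2), 94.44)

  # touching intervals do not overlap (half-open convention)
  touch <- event_metrics(
    tibble::tibble(start_s = 0, end_s = 10),
    tibble::tibble(start_s = 10, end_s = 20), 1
  )
  expect_equal(touch$n_detected_true, 0)
  expect_equal(touch$n_false_positives, 1)
})

test_that("event metrics agree with the exhaustive interval oracle", {
  for (seed in 1:100) {
    det <- random_intervals(1 + seed %% 8, 500, seed)
    ref <- random_intervals(1 + (seed * 7) %% 9, 500, seed + 5000)
    m <- event_metrics(det, ref, hours_evaluated = 0.5)
    o <- oracle_event_metrics(det, ref, 0.5)
    expect_equal(m$n_detected_true, unname(o["n_detected_true"]))
    expect_equal(m$n_false_positives, unname(o["n_false_positives"]))
    expect_equal(m$fdr_per_hour, unname(o["fdr_per_hour"]))
  }
})

test_that("collar extension never lowers event sensitivity", {
  for (seed in 1:25) {
    dec <- withr::with_seed(seed, rbinom(40, 1, 0.15))
    ref <- random_intervals(3, 150, seed + 100)
    base <- event_metrics(extract_events(dec), ref, 1)
    coll <- event_metrics(extract_events(collar_extend(dec, 2)), ref, 1)
    expect_gte(coll$n_detected_true, base$n_detected_true)
  }
})
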