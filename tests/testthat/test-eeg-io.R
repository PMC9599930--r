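test_that("plain-text records read back sample-for-sample with the stated rate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(1:10), path)
  rec <- read_eeg_txt(path, fs = 10)
  expect_s3_class(rec, "eeg_record")
  expect_equal(eeg_samples(rec)[, 1], as.numeric(1:10))
  expect_equal(eeg_duration(rec), 1.0)

  # a standard short intracranial segment: 4097 samples at 173.6 Hz ~ 23.6 s
  writeLines(as.character(round(rnorm(4097) * 100)), path)
  rec2 <- read_eeg_txt(path)
  expect_equal(eeg_duration(rec2), 4097 / 173.6)
  expect_equal(round(eeg_duration(rec2), 1), 23.6)

  # exact round-trip
  write_eeg_txt(rec2, path)
  expect_equal(eeg_samples(read_eeg_txt(path)), eeg_samples(rec2))
})

test_that("malformed text files raise format errors naming the line", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), path)
  expect_error(read_eeg_txt(path), "no samples")
  writeLines(c("1.5", "2.5", "oops", "4"), path)
  expect_error(read_eeg_txt(path), "line 3")
})

test_that("csv records enforce a rectangular numeric layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- matrix(rnorm(1024 * 3), ncol = 3)
  rec <- eeg_record(x, fs = 256, channel_names = c("A", "B", "C"))
  write_eeg_csv(rec, path)
  back <- read_eeg_csv(path, fs = 256)
  expect_equal(eeg_duration(back), 4.0)
  expect_equal(eeg_channels(back), c("A", "B", "C"))
  expect_equal(eeg_samples(back), eeg_samples(rec), ignore_attr = TRUE)

  writeLines(c("ch1", "1.25", "-3.5"), path)
  one <- read_eeg_csv(path, fs = 2)
  expect_equal(length(eeg_channels(one)), 1)
  expect_equal(eeg_samples(one)[, 1], c(1.25, -3.5))

  writeLines(c("a,b", "1,2", "3,oops"), path)
  expect_error(read_eeg_csv(path, fs = 1), "non-numeric")
  writeLines(c("a,b", "1,2", "3"), path)
  expect_error(read_eeg_csv(path, fs = 1), "field")
})

test_that("segmentation yields floor(duration/len) epochs of floor(len*fs) samples", {
  rec <- eeg_record(rnorm(4097), fs = 173.6)
  ep <- segment_epochs(rec, 4)
  expect_equal(nrow(ep), 5)
  expect_true(all(vapply(ep$signal, nrow, integer(1)) == 694))
  expect_equal(ep$start_s, c(0, 4, 8, 12, 16))
  # concatenating the epochs reproduces the leading samples exactly
  expect_equal(do.call(rbind, ep$signal)[, 1], eeg_samples(rec)[1:(5 * 694), 1])

  expect_equal(nrow(segment_epochs(eeg_record(rnorm(8 * 50), fs = 50), 4)), 2)
  expect_error(segment_epochs(eeg_record(rnorm(39), fs = 10), 4), "at least one full")
})

test_that("epoch labels follow the positive-overlap rule", {
  rec <- eeg_record(rnorm(120), fs = 10)
  ep <- segment_epochs(rec, 4)
  ann <- tibble::tibble(start_s = 5, end_s = 9)
  expect_equal(label_epochs(ep, ann)$label, c(0L, 1L, 1L))
  expect_equal(label_epochs(ep, tibble::tibble(start_s = numeric(), end_s = numeric()))$label, c(0L, 0L, 0L))
  expect_equal(label_epochs(ep, tibble::tibble(start_s = 0, end_s = 12))$label, c(1L, 1L, 1L))
  # boundary-touching interval has zero overlap with the half-open epoch
  expect_equal(label_epochs(ep, tibble::tibble(start_s = 4, end_s = 8))$label, c(0L, 1L, 0L))
})

test_that("enlarging an annotated interval never flips labels seizure -> nonseizure", {
  rec <- eeg_record(rnorm(400), fs = 10)
  ep <- segment_epochs(rec, 4)
  for (seed in 1:20) {
    iv <- withr::with_seed(seed, sort(runif(2, 0, 40)))
    small <- label_epochs(ep, tibble::tibble(start_s = iv[1], end_s = iv[2]))$label
    grown <- label_epochs(ep, tibble::tibble(
      start_s = max(0, iv[1] - 2), end_s = min(40, iv[2] + 2)
    ))$label
    expect_true(all(grown >= small))
  }
})

test_that("annotations validate and round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  ann <- tibble::tibble(start_s = c(3.5, 10), end_s = c(6, 14.25))
  write_annotations(ann, path)
  expect_equal(as.data.frame(read_annotations(path)), as.data.frame(ann))
  expect_error(
    eeg_record(rnorm(100), fs = 10, annotations = tibble::tibble(start_s = c(0, 2), end_s = c(3, 4))),
    "overlap"
  )
  expect_error(
    eeg_record(rnorm(100), fs = 10, annotations = tibble::tibble(start_s = 5, end_s = 4)),
    "start_s < end_s"
  )
  expect_error(
    eeg_record(rnorm(100), fs = 10, annotations = tibble::tibble(start_s = 5, end_s = 40)),
    "within the record"
  )
})
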