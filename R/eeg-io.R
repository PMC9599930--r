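#' Construct an EEG record
#'
#' An EEG record is a tibble with a `time_s` column and one numeric column per
#' channel, carrying the sampling rate and (optionally) expert seizure
#' annotations as attributes. Times are 0-based seconds; annotated intervals
#' are half-open `[start_s, end_s)`.
#'
#' @param samples Numeric vector (single channel) or matrix
#'   (`n_samples x n_channels`) of sample values, microvolt scale.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of channel identifiers;
#'   defaults to `ch1`, `ch2`, ...
#' @param annotations Optional tibble/data frame with columns `start_s`,
#'   `end_s` giving expert-marked seizure intervals in seconds from record
#'   start. Must be non-overlapping and lie within the record.
#' @return A tibble of class `eeg_record` with columns `time_s` and one per
#'   channel; attributes `fs` and `annotations`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 5 * (0:511) / 128), fs = 128)
#' eeg_duration(rec)
#' @export
eeg_record <- function(samples, fs, channel_names = NULL, annotations = NULL) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1 || ncol(samples) < 1) {
    abort("an EEG record needs at least one sample and one channel")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  channel_names <- channel_names %||% colnames(samples) %||%
    paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples)) {
    abort("`channel_names` must have one entry per channel")
  }
  channel_names <- make.unique(channel_names)
  duration <- nrow(samples) / fs
  annotations <- validate_annotations(annotations, duration)
  out <- tibble(time_s = (seq_len(nrow(samples)) - 1) / fs)
  for (j in seq_len(ncol(samples))) out[[channel_names[j]]] <- samples[, j]
  structure(out,
    fs = fs, annotations = annotations,
    class = c("eeg_record", class(out))
  )
}

validate_annotations <- function(annotations, duration) {
  if (is.null(annotations) || (is.data.frame(annotations) && nrow(annotations) == 0)) {
    return(tibble(start_s = numeric(), end_s = numeric()))
  }
  ann <- as_tibble(annotations)[, c("start_s", "end_s")]
  ann <- dplyr::arrange(ann, .data$start_s)
  if (any(ann$start_s >= ann$end_s)) abort("annotation intervals need start_s < end_s")
  if (any(ann$start_s < 0) || any(ann$end_s > duration + 1e-9)) {
    abort("annotation intervals must lie within the record duration")
  }
  if (nrow(ann) > 1 && any(ann$start_s[-1] < ann$end_s[-nrow(ann)])) {
    abort("annotation intervals must not overlap")
  }
  ann
}

#' @rdname eeg_record
#' @param record An `eeg_record`.
#' @export
eeg_fs <- function(record) attr(record, "fs")

#' @rdname eeg_record
#' @export
eeg_samples <- function(record) {
  as.matrix(record[, setdiff(names(record), "time_s"), drop = FALSE])
}

#' @rdname eeg_record
#' @export
eeg_channels <- function(record) setdiff(names(record), "time_s")

#' @rdname eeg_record
#' @export
eeg_duration <- function(record) (nrow(record)) / eeg_fs(record)

#' @rdname eeg_record
#' @export
annotations <- function(record) attr(record, "annotations")

#' @export
print.eeg_record <- function(x, ...) {
  ann <- annotations(x)
  cat(sprintf(
    "<eeg_record: %d channel(s), %.6g Hz, %.4g s, %d annotated interval(s)>\n",
    length(eeg_channels(x)), eeg_fs(x), eeg_duration(x),
    if (is.null(ann)) 0L else nrow(ann)
  ))
  NextMethod()
}

#' Read a single-channel plain-text EEG recording
#'
#' Reads the one-ASCII-number-per-line format used for short single-channel
#' EEG segments. Blank lines are ignored; any other unparseable line is a
#' format error naming the offending line.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz; the format itself carries none.
#' @return An [eeg_record()] with one channel, samples in file order.
#' @export
read_eeg_txt <- function(path, fs = 173.6) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop_format("'%s': file contains no samples", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop_format("'%s' line %d: cannot parse '%s' as a number", path, bad, lines[bad])
  }
  eeg_record(vals, fs = fs)
}

#' @rdname read_eeg_txt
#' @param record Single-channel `eeg_record` to write.
#' @export
write_eeg_txt <- function(record, path) {
  x <- eeg_samples(record)
  if (ncol(x) != 1) abort("write_eeg_txt() writes single-channel records only")
  writeLines(sprintf("%.17g", x[, 1]), path)
  invisible(path)
}

#' Read a multichannel CSV EEG recording
#'
#' Expects a header row of channel names followed by rectangular numeric rows,
#' one sample per row per channel. Ragged rows and non-numeric cells are
#' format errors.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @return An [eeg_record()] with one channel per column.
#' @export
read_eeg_csv <- function(path, fs) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop_format("'%s': need a header row and at least one sample row", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(cells[[1]])
  widths <- lengths(cells[-1])
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1] + 1L
    stop_format("'%s' line %d: %d field(s), expected %d", path, bad, widths[bad - 1L], length(header))
  }
  vals <- suppressWarnings(vapply(cells[-1], function(r) as.numeric(trimws(r)),
    numeric(length(header))
  ))
  vals <- matrix(vals, ncol = length(header), byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1] + 1L
    stop_format("'%s' line %d: non-numeric cell", path, bad)
  }
  eeg_record(vals, fs = fs, channel_names = header)
}

#' @rdname read_eeg_csv
#' @param record `eeg_record` to write.
#' @export
write_eeg_csv <- function(record, path) {
  x <- eeg_samples(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(eeg_channels(record), collapse = ","), con)
  writeLines(apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' Read or write seizure annotations
#'
#' Annotations are a CSV with columns `start_s`, `end_s` (seconds from record
#' start, half-open intervals).
#'
#' @param path Path to the annotations CSV.
#' @return A tibble with columns `start_s` and `end_s`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop_format("'%s': annotation files need 'start_s' and 'end_s' columns", path)
  }
  validate_annotations(df, Inf)
}

#' @rdname read_annotations
#' @param annotations Tibble with `start_s`, `end_s` columns.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("start_s", "end_s")], path, row.names = FALSE)
  invisible(path)
}

#' Segment a record into fixed-length non-overlapping epochs
#'
#' Cuts the record into contiguous epochs of `epoch_len_s` seconds starting at
#' time 0. Each epoch holds exactly `floor(epoch_len_s * fs)` samples, so a
#' non-integer product (e.g. 4 s at 173.6 Hz) yields a fixed 694-sample epoch.
#' Samples after the last full epoch are discarded.
#'
#' @param record An [eeg_record()].
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @return A tibble with one row per epoch: `epoch`, `start_s`,
#'   `epoch_len_s`, `fs`, and `signal` (a list-column of
#'   `epoch_samples x n_channels` matrices).
#' @examples
#' rec <- eeg_record(rnorm(2048), fs = 256)
#' segment_epochs(rec) # 2 epochs of 1024 samples
#' @export
segment_epochs <- function(record, epoch_len_s = 4) {
  fs <- eeg_fs(record)
  x <- eeg_samples(record)
  dur <- nrow(x) / fs
  if (dur < epoch_len_s) {
    abort(sprintf(
      "record is %.4g s long; need at least one full %.4g s epoch", dur, epoch_len_s
    ))
  }
  n_per <- floor(epoch_len_s * fs)
  n_ep <- floor(dur / epoch_len_s)
  sig <- lapply(seq_len(n_ep), function(i) {
    x[((i - 1) * n_per + 1):(i * n_per), , drop = FALSE]
  })
  tibble(
    epoch = seq_len(n_ep),
    start_s = (seq_len(n_ep) - 1) * epoch_len_s,
    epoch_len_s = epoch_len_s,
    fs = fs,
    signal = sig
  )
}

# Overlap (in seconds) of [start, start+len) with a set of half-open intervals.
interval_overlap_s <- function(start_s, len_s, intervals) {
  vapply(start_s, function(s) {
    if (nrow(intervals) == 0) return(0)
    sum(pmax(0, pmin(intervals$end_s, s + len_s) - pmax(intervals$start_s, s)))
  }, numeric(1))
}

#' Label epochs from annotated seizure intervals
#'
#' An epoch is labeled seizure (1) when its `[start_s, start_s + epoch_len_s)`
#' interval overlaps any annotated interval by more than `min_overlap_s`
#' seconds (default: any positive overlap).
#'
#' @param epochs Epoch tibble from [segment_epochs()].
#' @param annotations Tibble with `start_s`, `end_s` columns (or an
#'   `eeg_record`, whose annotations are used).
#' @param min_overlap_s Overlap (s) strictly above which an epoch is seizure.
#' @return `epochs` with an integer `label` column (1 = seizure).
#' @export
label_epochs <- function(epochs, annotations, min_overlap_s = 0) {
  if (inherits(annotations, "eeg_record")) annotations <- annotations(annotations)
  annotations <- annotations %||% tibble(start_s = numeric(), end_s = numeric())
  ov <- interval_overlap_s(epochs$start_s, epochs$epoch_len_s[1], annotations)
  dplyr::mutate(epochs, label = as.integer(ov > min_overlap_s))
}
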