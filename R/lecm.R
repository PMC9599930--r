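#' Regularized sample covariance of a time-frequency matrix
#'
#' Column-mean-removed sample covariance with the `n - 1` divisor, plus a tiny
#' ridge `1e-10 * trace(C)/d` on the diagonal so the result is symmetric
#' positive-definite even when columns are collinear, keeping the matrix
#' logarithm well-defined.
#'
#' @param X Numeric matrix with at least 2 rows (observations) and 2 columns.
#' @return A symmetric positive-definite `d x d` matrix.
#' @export
spd_cov <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("covariance needs at least 2 rows")
  C <- cov(X)
  d <- ncol(C)
  ridge <- 1e-10 * sum(diag(C)) / d
  C + diag(ridge, d)
}

check_square_symmetric <- function(M, what) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort(sprintf("%s needs a square matrix", what))
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    abort(sprintf("%s needs a symmetric matrix", what))
  }
  M
}

#' Matrix logarithm and exponential of a symmetric matrix
#'
#' For a symmetric positive-definite matrix `C = U diag(lambda) U'`,
#' `spd_logm()` returns `U diag(log lambda) U'` -- the log-Euclidean map that
#' carries the SPD manifold to the vector space of symmetric matrices, where
#' Euclidean operations on covariance features are valid. `spd_expm()` is its
#' inverse.
#'
#' @param C Symmetric positive-definite matrix (for `spd_logm`).
#' @return A symmetric matrix of the same dimension.
#' @examples
#' spd_logm(diag(c(4, 1))) # diag(log 4, 0)
#' @export
spd_logm <- function(C) {
  C <- check_square_symmetric(C, "spd_logm()")
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0) {
    abort(sprintf(
      "matrix is not positive definite (min eigenvalue = %.3g); cannot take its logarithm",
      min(e$values)
    ))
  }
  S <- e$vectors %*% (log(e$values) * t(e$vectors))
  (S + t(S)) / 2
}

#' @rdname spd_logm
#' @param S Symmetric matrix (for `spd_expm`).
#' @export
spd_expm <- function(S) {
  S <- check_square_symmetric(S, "spd_expm()")
  e <- eigen(S, symmetric = TRUE)
  M <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (M + t(M)) / 2
}

#' Half-vectorize a symmetric matrix
#'
#' Stacks the diagonal and above-diagonal entries column-wise:
#' `C11, C12, C22, C13, C23, C33, ..., Cdd`, giving a vector of length
#' `d(d+1)/2`. Entries below the diagonal are redundant for a symmetric
#' matrix and are dropped; no off-diagonal weighting is applied.
#'
#' @param S Square symmetric matrix.
#' @return Numeric vector of length `d(d+1)/2`.
#' @export
half_vectorize <- function(S) {
  S <- check_square_symmetric(S, "half_vectorize()")
  S[upper.tri(S, diag = TRUE)]
}

# One epoch (samples x channels matrix) -> LECM feature vector.
lecm_vector <- function(epoch, fs, selected_modes, K, alpha, tau, tol, max_iter,
                        vmfsets = NULL) {
  vmfsets <- vmfsets %||% lapply(seq_len(ncol(epoch)), function(j) {
    vmd(epoch[, j], fs, K = K, alpha = alpha, tau = tau, tol = tol, max_iter = max_iter)
  })
  tf <- build_tf_matrix(vmfsets, selected_modes)
  half_vectorize(spd_logm(spd_cov(tf)))
}

#' Log-Euclidean covariance features for labeled epochs
#'
#' The full feature map of the detector: each epoch's channels are decomposed
#' with [vmd()], the retained modes are stacked into a time-frequency matrix
#' ([build_tf_matrix()]), and its covariance is carried through the matrix
#' logarithm ([spd_logm()]) and half-vectorized. With `s` retained modes over
#' `c` channels the feature has length `m(m+1)/2`, `m = c * s` (6 for one
#' channel and 3 modes, 45 for three channels and 3 modes).
#'
#' Mode screening: when `selected_modes` is `NULL` the absolute Pearson
#' correlation of each frequency-ranked mode with its raw signal is averaged
#' over all epochs and channels, and modes with mean correlation above
#' `cor_threshold` are retained -- fix the selection on training data and pass
#' it explicitly for test data.
#'
#' @param epochs Epoch tibble from [segment_epochs()] (optionally labeled).
#' @param K,alpha,tau,tol,max_iter VMD parameters, see [vmd()].
#' @param selected_modes Integer indices of modes (ascending center-frequency
#'   order) to retain, or `NULL` to screen by correlation on these epochs.
#' @param cor_threshold Correlation threshold for screening.
#' @return A tibble with `epoch`, `start_s`, `label` (if present in `epochs`)
#'   and feature columns `f1 ... fm`; the retained mode indices are attached
#'   as attribute `selected_modes` and the per-mode mean correlations as
#'   attribute `mode_correlations`.
#' @export
lecm_features <- function(epochs, K = 5, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500, selected_modes = NULL,
                          cor_threshold = 0.3) {
  if (nrow(epochs) == 0) abort("no epochs to featurize")
  fs <- epochs$fs[1]
  decomps <- lapply(epochs$signal, function(ep) {
    lapply(seq_len(ncol(ep)), function(j) {
      vmd(ep[, j], fs, K = K, alpha = alpha, tau = tau, tol = tol, max_iter = max_iter)
    })
  })
  mean_r <- NULL
  if (is.null(selected_modes)) {
    rs <- purrr::map(seq_len(nrow(epochs)), function(i) {
      vapply(seq_along(decomps[[i]]), function(j) {
        mode_correlations(decomps[[i]][[j]])$r
      }, numeric(K))
    })
    mean_r <- rowMeans(do.call(cbind, rs))
    selected_modes <- select_by_correlation(mean_r, cor_threshold)
    if (length(selected_modes) == 0) {
      abort("no mode exceeds the correlation threshold; nothing to retain")
    }
  }
  feats <- t(vapply(
    seq_len(nrow(epochs)),
    function(i) {
      lecm_vector(epochs$signal[[i]], fs, selected_modes,
        K, alpha, tau, tol, max_iter,
        vmfsets = decomps[[i]]
      )
    },
    numeric(length(selected_modes) * ncol(epochs$signal[[1]]) *
      (length(selected_modes) * ncol(epochs$signal[[1]]) + 1) / 2)
  ))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  keep <- intersect(c("epoch", "start_s", "label"), names(epochs))
  out <- dplyr::bind_cols(epochs[, keep], as_tibble(feats))
  attr(out, "selected_modes") <- selected_modes
  attr(out, "mode_correlations") <- mean_r
  out
}

feature_columns <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

feature_matrix <- function(data) {
  cols <- feature_columns(data)
  if (length(cols) == 0) abort("no feature columns (f1, f2, ...) found")
  as.matrix(data[, cols])
}
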