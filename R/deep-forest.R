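#' Deep-forest classifier for LECM epoch features
#'
#' A non-neural deep ensemble in the gcForest style. Multigrain scanning
#' slides windows (default lengths 5 and 3, stride 1) over the feature
#' vector; each window instance is classified by a random forest and a
#' completely-random forest, and their class probabilities are concatenated
#' into the scanned representation. A cascade of levels is then grown, each
#' level holding two random forests and two completely-random forests; the
#' input of level `t` is the scanned representation concatenated with the
#' class vectors of level `t - 1`. During training the class vectors passed
#' forward are out-of-fold cross-validated predictions, and growth stops
#' adaptively when the mean cross-validated accuracy stops improving; the
#' depth with the best accuracy is kept.
#'
#' Forest kinds: "random" splits on the best of `floor(sqrt(d))` candidate
#' features; "completely random" splits one randomly chosen feature at one
#' randomly chosen threshold, grown to purity. Both are fitted with
#' \pkg{ranger} as 120-tree probability forests by default. All randomness
#' derives from the single `seed`, so equal seeds give identical models and
#' predictions.
#'
#' @param data Data frame with feature columns `f1 ... fd` (as produced by
#'   [lecm_features()]) and an integer `label` column (1 = seizure,
#'   0 = nonseizure).
#' @param windows Multigrain window lengths; each must be at most the feature
#'   dimension.
#' @param trees Trees per cascade forest.
#' @param scan_trees Trees per scanning forest.
#' @param cv_folds Folds for the out-of-fold class vectors (each class must
#'   have at least this many training samples).
#' @param max_levels Cap on cascade depth.
#' @param patience Levels without improvement tolerated before stopping.
#' @param min_improvement Minimum absolute accuracy gain that counts as an
#'   improvement.
#' @param seed Integer seed driving every forest and fold assignment.
#' @return An object of class `deep_forest`.
#' @export
fit_deep_forest <- function(data, windows = c(5, 3), trees = 120,
                            scan_trees = trees, cv_folds = 3, max_levels = 20,
                            patience = 1, min_improvement = 1e-4, seed = 1) {
  X <- if (is.matrix(data)) data else feature_matrix(data)
  if (!all(is.finite(X))) abort("features contain NA/NaN/Inf values")
  if (!"label" %in% names(as.data.frame(data))) abort("`data` needs a `label` column")
  y_raw <- as.data.frame(data)$label
  if (!all(y_raw %in% c(0, 1))) abort("`label` must be binary 0/1")
  classes <- c("nonseizure", "seizure")
  y <- factor(classes[y_raw + 1], levels = classes)
  if (nlevels(droplevels(y)) < 2) abort("training data must contain both classes")
  if (min(table(y)) < cv_folds) {
    abort(sprintf("each class needs at least cv_folds = %d samples", cv_folds))
  }
  d <- ncol(X)
  windows <- sort(as.integer(windows), decreasing = TRUE)
  if (any(windows < 1) || any(windows > d)) {
    abort(sprintf("window lengths must be in [1, %d] (feature dimension)", d))
  }
  if (max_levels < 1 || trees < 1 || cv_folds < 2) {
    abort("need max_levels >= 1, trees >= 1, cv_folds >= 2")
  }

  pool <- derive_seeds(seed, 2L * length(windows) + 4L * max_levels * (cv_folds + 1L) + 1L)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  next_seed <- function() {
    counter$i <- counter$i + 1L
    pool[counter$i]
  }

  # ---- multigrain scanning forests ----------------------------------------
  scan <- lapply(windows, function(w) {
    inst <- window_instances(X, w)
    yy <- rep(y, times = nrow(inst) / nrow(X))
    list(
      w = w,
      rf = fit_forest(inst, yy, "random", scan_trees, next_seed()),
      crf = fit_forest(inst, yy, "completely_random", scan_trees, next_seed())
    )
  })
  model <- structure(
    list(
      scan = scan, windows = windows, d = d, classes = classes,
      trees = trees, scan_trees = scan_trees, cv_folds = cv_folds,
      patience = patience, min_improvement = min_improvement, seed = seed
    ),
    class = "deep_forest"
  )
  # training-time scanned representation uses out-of-bag probabilities, so
  # the cascade's cross-validated accuracies are not inflated by the
  # scanning forests having seen the very rows they describe
  Z <- scan_matrix_oob(model, nrow(X))

  # ---- adaptive cascade ---------------------------------------------------
  folds <- stratified_folds(y, cv_folds, next_seed())
  kinds <- c("random", "random", "completely_random", "completely_random")
  levels_fits <- list()
  level_acc <- numeric(0)
  prev <- NULL
  best <- -Inf
  stale <- 0L
  for (t in seq_len(max_levels)) {
    input <- level_input(Z, prev)
    fits <- vector("list", 4)
    oofs <- vector("list", 4)
    for (j in 1:4) {
      res <- oof_forest(input, y, kinds[j], trees, folds,
        seeds = vapply(seq_len(cv_folds + 1L), function(i) next_seed(), integer(1)),
        classes = classes
      )
      fits[[j]] <- res$fit
      oofs[[j]] <- res$oof
    }
    avg <- Reduce(`+`, oofs) / 4
    acc <- mean((avg[, 2] > avg[, 1]) == (y == classes[2]))
    levels_fits[[t]] <- fits
    level_acc[t] <- acc
    prev <- class_vector_matrix(oofs)
    if (acc > best + min_improvement) {
      best <- acc
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale >= patience) break
  }
  model$levels <- levels_fits
  model$level_accuracy <- level_acc
  model$n_levels <- which.max(level_acc) # ties favor the shallower depth
  model
}

# All sliding windows of length w, stride 1, stacked block-wise by position:
# rows 1..n are window position 1, rows n+1..2n position 2, ...
window_instances <- function(X, w) {
  n <- nrow(X)
  pos <- seq_len(ncol(X) - w + 1L)
  inst <- do.call(rbind, lapply(pos, function(p) X[, p + seq_len(w) - 1L, drop = FALSE]))
  colnames(inst) <- paste0("w", seq_len(w))
  inst
}

fit_forest <- function(X, y, kind, trees, seed) {
  df <- as.data.frame(X)
  df$.y <- y
  args <- list(
    dependent.variable.name = ".y", data = df, num.trees = trees,
    probability = TRUE, min.node.size = 1, seed = seed,
    num.threads = 1, verbose = FALSE
  )
  if (kind == "completely_random") {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1
    args$mtry <- 1
  } else {
    args$mtry <- max(1L, floor(sqrt(ncol(X))))
  }
  do.call(ranger::ranger, args)
}

pred_forest <- function(fit, X, classes) {
  p <- predict(fit, data = as.data.frame(X), num.threads = 1, verbose = FALSE)$predictions
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

oof_forest <- function(X, y, kind, trees, folds, seeds, classes) {
  oof <- matrix(NA_real_, length(y), length(classes))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- fit_forest(X[tr, , drop = FALSE], y[tr], kind, trees, seeds[f])
    oof[!tr, ] <- pred_forest(fit, X[!tr, , drop = FALSE], classes)
  }
  list(fit = fit_forest(X, y, kind, trees, seeds[length(seeds)]), oof = oof)
}

class_vector_matrix <- function(prob_list) {
  q <- do.call(cbind, prob_list)
  colnames(q) <- paste0("q", seq_len(ncol(q)))
  q
}

level_input <- function(Z, prev) {
  if (is.null(prev)) Z else cbind(Z, prev)
}

# Scanned representation: per grain (window-length-descending), per window
# position (ascending), per forest (random then completely random), the
# class-probability pair.
assemble_scan <- function(prob_pairs, n) {
  blocks <- lapply(prob_pairs, function(pp) {
    npos <- nrow(pp$rf) / n
    out <- matrix(0, n, npos * 4L)
    for (p in seq_len(npos)) {
      rows <- (p - 1L) * n + seq_len(n)
      out[, (p - 1L) * 4L + 1:2] <- pp$rf[rows, ]
      out[, (p - 1L) * 4L + 3:4] <- pp$crf[rows, ]
    }
    out
  })
  Z <- do.call(cbind, blocks)
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

scan_matrix <- function(model, X) {
  assemble_scan(lapply(model$scan, function(g) {
    inst <- window_instances(X, g$w)
    list(
      rf = pred_forest(g$rf, inst, model$classes),
      crf = pred_forest(g$crf, inst, model$classes)
    )
  }), nrow(X))
}

# Out-of-bag class probabilities of the training window instances.
oob_probs <- function(fit, classes) {
  p <- fit$predictions
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  # rows that were in-bag for every tree have no OOB estimate
  out[!is.finite(out[, 1]), ] <- 1 / length(classes)
  out
}

scan_matrix_oob <- function(model, n) {
  assemble_scan(lapply(model$scan, function(g) {
    list(rf = oob_probs(g$rf, model$classes), crf = oob_probs(g$crf, model$classes))
  }), n)
}

#' Multigrain-scan features through a fitted model's scanning forests
#'
#' Returns the scanned (augmented) representation: for each grain of window
#' length `w`, `(d - w + 1)` windows times 2 forests times 2 class
#' probabilities, grains concatenated in window-length-descending order.
#'
#' @param object A fitted `deep_forest`.
#' @param data Feature data frame (columns `f1...fd`) or matrix.
#' @return Numeric matrix of scanned features, one row per input row.
#' @export
multigrain_scan <- function(object, data) {
  X <- if (is.matrix(data)) data else feature_matrix(data)
  check_dim(object, X)
  scan_matrix(object, X)
}

check_dim <- function(object, X) {
  if (ncol(X) != object$d) {
    abort(sprintf(
      "feature dimension %d does not match the %d the model was trained on",
      ncol(X), object$d
    ))
  }
  if (!all(is.finite(X))) abort("features contain NA/NaN/Inf values")
  invisible(X)
}

#' Predict seizure probabilities from a deep forest
#'
#' Runs the scanned representation through the retained cascade levels; the
#' prediction is the average of the final level's four forest class vectors.
#' Probability rows sum to 1, class order `[nonseizure, seizure]`.
#'
#' @param object A fitted `deep_forest`.
#' @param data Feature data frame (columns `f1...fd`) or matrix.
#' @param type `"prob"` for a probability tibble, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return A tibble with columns `p_nonseizure`, `p_seizure`, or an integer
#'   vector of 0/1 labels.
#' @export
predict.deep_forest <- function(object, data, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(data)) data else feature_matrix(data)
  check_dim(object, X)
  Z <- scan_matrix(object, X)
  prev <- NULL
  for (t in seq_len(object$n_levels)) {
    input <- level_input(Z, prev)
    probs <- lapply(object$levels[[t]], function(f) pred_forest(f, input, object$classes))
    prev <- class_vector_matrix(probs)
  }
  avg <- Reduce(`+`, probs) / length(probs)
  if (type == "class") {
    return(as.integer(avg[, 2] > avg[, 1]))
  }
  tibble(p_nonseizure = avg[, 1], p_seizure = avg[, 2])
}

#' @export
print.deep_forest <- function(x, ...) {
  cat(sprintf(
    "<deep_forest: %d cascade level(s) kept of %d grown; windows %s; %d trees/forest>\n",
    x$n_levels, length(x$level_accuracy),
    paste(x$windows, collapse = "/"), x$trees
  ))
  cat(sprintf(
    "  cross-validated accuracy by level: %s\n",
    paste(sprintf("%.4f", x$level_accuracy), collapse = ", ")
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.deep_forest <- function(x, ...) {
  tibble(
    level = seq_along(x$level_accuracy),
    cv_accuracy = x$level_accuracy,
    kept = seq_along(x$level_accuracy) <= x$n_levels
  )
}

#' @exportS3Method generics::glance
glance.deep_forest <- function(x, ...) {
  tibble(
    n_levels = x$n_levels,
    n_levels_grown = length(x$level_accuracy),
    best_cv_accuracy = max(x$level_accuracy),
    trees_per_forest = x$trees,
    windows = paste(x$windows, collapse = "/"),
    seed = x$seed
  )
}
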