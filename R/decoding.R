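#' Build a decoding dataset: empirical versus temporally desynchronized
#'
#' Class 0 is the empirical per-event epoch activity; class 1 is the same
#' extraction applied to traces in which every neuron's session-long series
#' has been circularly rotated by an independent uniform offset, which
#' destroys event locking while preserving each trace's statistics. Features
#' are z-scored per column after stacking the two classes.
#'
#' Two feature constructions are available: \code{"matrix"} (events x
#' neurons, the standard per-subject decoder) and \code{"scalar"} (all
#' (neuron, event) epoch means vertically stacked as a single feature).
#'
#' Epoch means are computed on per-trial z-scored peri-event windows, the
#' same substrate as every other analysis stage; the per-trial z-scoring
#' removes slow baseline offsets that would otherwise let a classifier
#' separate two rotations by their drift levels alone.
#'
#' @param traces a \code{\link{trace_matrix}}.
#' @param event_times anchor times of the events (s).
#' @param epoch an \code{\link{epoch_window}} relative to the anchors.
#' @param window full extraction window used for per-trial z-scoring (s);
#'   must contain the epoch.
#' @param seed integer seed for the rotation offsets.
#' @param mode feature construction, \code{"matrix"} or \code{"scalar"}.
#' @param both_shuffled build both classes from independent rotations (the
#'   chance-level baseline construction).
#' @return list of class \code{decoding_set}: \code{x} (feature matrix),
#'   \code{y} (factor: empirical/shuffle), \code{mode}.
#' @export
build_decoding_sets <- function(traces, event_times, epoch, seed = 1L,
                                mode = c("matrix", "scalar"),
                                window = c(-10, 10),
                                both_shuffled = FALSE) {
  mode <- match.arg(mode)
  n_samp <- ncol(traces$values)
  win_len <- (window[2L] - window[1L]) * traces$rate_hz
  if (n_samp < 2L * win_len)
    stop("trace too short to rotate meaningfully (< 2x extraction window)",
         call. = FALSE)
  extract_means <- function(tm) {
    tens <- zscore_per_trial(extract_peri_event(tm, event_times, window))
    t(epoch_mean(tens, epoch))  # events x neurons
  }
  rotate_traces <- function(tm) {
    v <- tm$values
    for (i in seq_len(nrow(v)))
      v[i, ] <- circ_shift(v[i, ], sample.int(n_samp, 1L))
    trace_matrix(v, tm$rate_hz)
  }
  with_seed(seed, {
    cls0 <- if (both_shuffled) extract_means(rotate_traces(traces))
      else extract_means(traces)
    cls1 <- extract_means(rotate_traces(traces))
    if (mode == "scalar") {
      cls0 <- matrix(as.vector(cls0), ncol = 1L)
      cls1 <- matrix(as.vector(cls1), ncol = 1L)
    }
    x <- rbind(cls0, cls1)
    x <- scale(x)
    x[, attr(x, "scaled:scale") < .Machine$double.eps^0.5] <- 0
    y <- factor(rep(c("empirical", "shuffle"),
                    c(nrow(cls0), nrow(cls1))))
    structure(list(x = as.matrix(x), y = y, mode = mode),
              class = "decoding_set")
  })
}

f1_score <- function(truth, pred, positive = "empirical") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-validated linear decoding of a dataset
#'
#' Linear maximum-margin (SVM) classification with stratified k-fold
#' cross-validation; performance is the F1 score on each held-out fold
#' (positive class: empirical). Regularization is fixed (cost = 1); no
#' hyperparameter search is performed.
#'
#' @param dataset a \code{decoding_set}.
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return list with \code{fold_f1}, \code{mean_f1}, \code{n_folds},
#'   \code{mode}.
#' @export
decode_vs_shuffle <- function(dataset, n_folds = 5L, seed = 1L) {
  x <- dataset$x
  y <- dataset$y
  if (min(table(y)) < n_folds)
    stop("too few observations per class for ", n_folds, "-fold ",
         "stratified cross-validation", call. = FALSE)
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    f
  })
  fold_f1 <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    f1_score(y[!tr], pred)
  }, numeric(1L))
  list(fold_f1 = fold_f1, mean_f1 = mean(fold_f1), n_folds = n_folds,
       mode = dataset$mode)
}

#' Decode ensemble activity against its shuffle, with chance baseline
#'
#' Runs the full decoding control for one ensemble/epoch: builds the
#' empirical-versus-shuffle dataset, decodes it, then builds and decodes a
#' shuffle-versus-shuffle dataset of the same geometry as the chance-level
#' baseline.
#'
#' @inheritParams build_decoding_sets
#' @param n_folds cross-validation folds.
#' @return an object of class \code{decoding_result}: list with
#'   \code{fold_f1}, \code{mean_f1}, \code{baseline_fold_f1},
#'   \code{baseline_mean_f1}, \code{n_folds}, \code{mode}.
#' @export
decode_ensemble <- function(traces, event_times, epoch, seed = 1L,
                            mode = c("matrix", "scalar"), n_folds = 5L) {
  mode <- match.arg(mode)
  ds <- build_decoding_sets(traces, event_times, epoch, seed = seed,
                            mode = mode)
  res <- decode_vs_shuffle(ds, n_folds = n_folds, seed = seed)
  ds0 <- build_decoding_sets(traces, event_times, epoch,
                             seed = derive_seed(seed, "baseline"),
                             mode = mode, both_shuffled = TRUE)
  res0 <- decode_vs_shuffle(ds0, n_folds = n_folds,
                            seed = derive_seed(seed, "baseline_folds"))
  structure(list(fold_f1 = res$fold_f1, mean_f1 = res$mean_f1,
                 baseline_fold_f1 = res0$fold_f1,
                 baseline_mean_f1 = res0$mean_f1,
                 n_folds = n_folds, mode = mode),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding (", x$mode, " features, ", x$n_folds, "-fold): mean F1 ",
      round(x$mean_f1, 3), " vs shuffle baseline ",
      round(x$baseline_mean_f1, 3), "\n", sep = "")
  invisible(x)
}
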