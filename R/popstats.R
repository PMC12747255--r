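#' Ensemble population vector
#'
#' Mean epoch-window activity per neuron, averaged across the selected
#' events: the per-ensemble template that is correlated against ongoing
#' population activity.
#'
#' @param tensor a \code{peri_event_tensor}.
#' @param epoch an \code{\link{epoch_window}}.
#' @param events optional integer subset of events (default: all).
#' @return numeric vector over neurons.
#' @export
population_vector <- function(tensor, epoch, events = NULL) {
  em <- epoch_mean(tensor, epoch)
  if (is.null(events)) events <- seq_len(ncol(em))
  if (!length(events)) stop("empty event set", call. = FALSE)
  rowMeans(em[, events, drop = FALSE])
}

#' Population-vector correlation series
#'
#' Correlates an ensemble population vector with the instantaneous
#' population activity vector in rebinned (default 100 ms) session-long
#' activity: a per-bin Pearson r tracking how strongly the ensemble's
#' template is expressed over time.
#'
#' @param pv population vector (length = number of neurons).
#' @param traces a \code{\link{trace_matrix}} with the same neurons.
#' @param bin_s rebinned bin width (s); native samples are averaged.
#' @return an object of class \code{pv_series}: list with \code{r} (per-bin
#'   correlations, NA where activity had zero variance), \code{time_s} (bin
#'   centers) and \code{bin_s}.
#' @export
pv_correlation_series <- function(pv, traces, bin_s = 0.1) {
  stopifnot(inherits(traces, "trace_matrix"))
  n <- nrow(traces$values)
  if (length(pv) != n)
    stop("population vector length must equal the number of neurons",
         call. = FALSE)
  if (n < 3L)
    stop("population-vector correlation needs at least 3 neurons",
         call. = FALSE)
  per <- max(1L, round(bin_s * traces$rate_hz))
  n_bins <- ncol(traces$values) %/% per
  v <- traces$values[, seq_len(n_bins * per), drop = FALSE]
  dim(v) <- c(n, per, n_bins)
  binned <- colMeans(aperm(v, c(2L, 1L, 3L)), dims = 1L)  # n x n_bins
  sds <- apply(binned, 2L, stats::sd)
  r <- rep(NA_real_, n_bins)
  ok <- sds > .Machine$double.eps^0.5
  if (stats::sd(pv) > .Machine$double.eps^0.5 && any(ok))
    r[ok] <- as.numeric(stats::cor(pv, binned[, ok, drop = FALSE]))
  structure(list(r = r, time_s = (seq_len(n_bins) - 0.5) * per /
                   traces$rate_hz, bin_s = per / traces$rate_hz),
            class = "pv_series")
}

#' @export
print.pv_series <- function(x, ...) {
  cat("PV correlation series:", length(x$r), "bins of", x$bin_s, "s; mean r",
      round(mean(x$r, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Safe-versus-risky contrast of PV correlations
#'
#' Extracts, per trial, the mean PV correlation within the epoch window
#' around the trial's anchor event, then contrasts safe-block and
#' risky-block trials. Across-subject paired tests are computed by
#' \code{\link{paired_block_t}} on the per-subject block means.
#'
#' @param series a \code{pv_series}.
#' @param anchor_times per-trial anchor event times (s).
#' @param blocks per-trial block ids (block 1 = safe, blocks >= 2 = risky).
#' @param epoch an \code{\link{epoch_window}} relative to the anchor.
#' @return list with \code{trial_means} (data frame: block, anchor, mean_r),
#'   \code{mean_safe}, \code{mean_risky}, and a Welch t-test across trials
#'   (\code{t_statistic}, \code{p_value}).
#' @export
pv_block_contrast <- function(series, anchor_times, blocks, epoch) {
  stopifnot(length(anchor_times) == length(blocks))
  if (length(unique(blocks >= 2L)) < 2L)
    stop("both safe and risky blocks must be represented", call. = FALSE)
  mr <- vapply(anchor_times, function(a) {
    sel <- series$time_s >= a + epoch$start_s &
      series$time_s < a + epoch$end_s
    if (!any(sel)) return(NA_real_)
    mean(series$r[sel], na.rm = TRUE)
  }, numeric(1L))
  tm <- data.frame(block = blocks, anchor = anchor_times, mean_r = mr)
  safe <- mr[blocks == 1L]
  risky <- mr[blocks >= 2L]
  tt <- if (stats::sd(c(safe, risky), na.rm = TRUE) <
            .Machine$double.eps^0.5)
    list(statistic = c(t = 0), p.value = 1)
  else stats::t.test(safe, risky)
  list(trial_means = tm,
       mean_safe = mean(safe, na.rm = TRUE),
       mean_risky = mean(risky, na.rm = TRUE),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Paired t-test on per-subject block means
#'
#' @param safe,risky per-subject means (equal length, paired).
#' @return list with \code{t_statistic}, \code{p_value}, \code{mean_diff}.
#' @export
paired_block_t <- function(safe, risky) {
  stopifnot(length(safe) == length(risky))
  d <- safe - risky
  if (stats::sd(d) < .Machine$double.eps^0.5)
    return(list(t_statistic = 0, p_value = 1, mean_diff = mean(d)))
  tt <- stats::t.test(safe, risky, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d))
}

#' Pairwise correlations between neurons' mean event-aligned traces
#'
#' Correlates every neuron's trial-averaged event-aligned trace with every
#' other's, and summarizes the fractions of positive, negative and neutral
#' pairs within and across ensemble groups. The neutral band is |r| <
#' \code{neutral_band}.
#'
#' @param mean_traces neurons x bins matrix of trial-averaged activity.
#' @param groups per-neuron group labels (e.g. ensemble identities).
#' @param neutral_band half-width of the neutral correlation band.
#' @return list with \code{matrix} (full correlation matrix; pairs involving
#'   constant rows are NA) and \code{summary}, a data frame per group pair
#'   with \code{frac_pos}, \code{frac_neg}, \code{frac_neutral}.
#' @export
pairwise_ensemble_correlations <- function(mean_traces, groups = NULL,
                                           neutral_band = 0.1) {
  x <- as.matrix(mean_traces)
  if (nrow(x) < 2L) stop("need at least 2 neurons", call. = FALSE)
  sds <- apply(x, 1L, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  if (any(const))
    warning(sum(const), " constant row(s): their pairs are undefined (NA)",
            call. = FALSE)
  cm <- suppressWarnings(stats::cor(t(x)))
  cm[const, ] <- NA
  cm[, const] <- NA
  diag(cm) <- 1
  out <- list(matrix = cm, summary = NULL)
  if (!is.null(groups)) {
    gs <- unique(groups)
    rows <- list()
    for (i in seq_along(gs)) for (j in i:length(gs)) {
      a <- which(groups == gs[i])
      b <- which(groups == gs[j])
      pr <- if (i == j) {
        if (length(a) < 2L) numeric(0)
        else cm[a, a][upper.tri(matrix(0, length(a), length(a)))]
      } else as.vector(cm[a, b, drop = FALSE])
      pr <- pr[!is.na(pr)]
      n_pairs <- length(pr)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gs[i], group_b = gs[j], n_pairs = n_pairs,
        frac_pos = if (n_pairs) mean(pr >= neutral_band) else NA_real_,
        frac_neg = if (n_pairs) mean(pr <= -neutral_band) else NA_real_,
        frac_neutral = if (n_pairs) mean(abs(pr) < neutral_band)
          else NA_real_)
    }
    out$summary <- do.call(rbind, rows)
  }
  out
}

#' Correlate trial-wise epoch activity with a behavioral variable
#'
#' Per neuron, the Pearson correlation between its per-trial epoch means and
#' a per-trial behavioral variable (e.g. choice latency); the distribution of
#' correlations in a target ensemble is compared against a comparison group
#' with a two-sample KS test (distributions) and an unpaired t-test (means).
#'
#' @param epoch_means neurons x trials matrix.
#' @param behavior per-trial behavioral values.
#' @param target_idx,comparison_idx neuron index sets to compare.
#' @return list with \code{r} (per-neuron correlations), \code{ks_statistic},
#'   \code{ks_p}, \code{t_statistic}, \code{t_p}.
#' @export
behavior_activity_correlation <- function(epoch_means, behavior,
                                          target_idx, comparison_idx) {
  if (ncol(epoch_means) != length(behavior))
    stop("behavior must have one value per trial", call. = FALSE)
  if (length(behavior) < 10L)
    stop("need at least 10 trials", call. = FALSE)
  if (stats::sd(behavior) < .Machine$double.eps^0.5)
    stop("behavioral variable is constant", call. = FALSE)
  r <- suppressWarnings(
    as.numeric(stats::cor(t(epoch_means), behavior)))
  ra <- r[target_idx]
  rb <- r[comparison_idx]
  if (length(ra) < 2L || length(rb) < 2L)
    return(list(r = r, ks_statistic = NA_real_, ks_p = NA_real_,
                t_statistic = NA_real_, t_p = NA_real_))
  ks <- suppressWarnings(stats::ks.test(ra, rb))
  tt <- stats::t.test(ra, rb)
  list(r = r, ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       t_statistic = unname(tt$statistic), t_p = tt$p.value)
}

#' PCA trajectory divergence between two event types with a rotation null
#'
#' Horizontally concatenates the two event-aligned mean matrices, z-scores
#' each neuron's concatenated series, extracts principal components, and
#' projects each event's data on PCs 1-2. The per-bin absolute difference of
#' the two PC1 trajectories is compared against a null built by repeating
#' the whole procedure on data where every neuron's series is independently
#' circularly rotated. Because \code{n_null = 100} rotations cannot resolve a
#' 0.001 quantile, the operational rule is strict exceedance of the per-bin
#' null maximum (effective alpha 1/(n_null + 1)); raise \code{n_null} for a
#' true quantile rule. Runs shorter than \code{min_run} bins are discarded.
#'
#' @param mat_a,mat_b neurons x bins matrices of trial-averaged activity for
#'   the two events (same neurons, same bins).
#' @param n_null number of circular-rotation null iterations.
#' @param alpha nominal alpha.
#' @param min_run minimum consecutive significant bins.
#' @param seed integer seed.
#' @return list with \code{projection_a}, \code{projection_b} (bins x 2),
#'   \code{distance} (per-bin |PC1 difference|), \code{null_max} (per-bin
#'   null envelope), \code{mask} (a \code{significance_mask}) and
#'   \code{effective_alpha}.
#' @export
pca_trajectory_divergence <- function(mat_a, mat_b, n_null = 100L,
                                      alpha = 0.001, min_run = 10L,
                                      seed = 1L) {
  stopifnot(all(dim(mat_a) == dim(mat_b)))
  if (nrow(mat_a) < 2L) stop("need at least 2 neurons", call. = FALSE)
  tbins <- ncol(mat_a)
  run_once <- function(a, b) {
    x <- cbind(a, b)
    mu <- rowMeans(x)
    sd0 <- apply(x, 1L, stats::sd)
    sd0[sd0 < .Machine$double.eps^0.5] <- 1
    xz <- (x - mu) / sd0
    pc <- stats::prcomp(t(xz), center = FALSE, scale. = FALSE)
    w <- pc$rotation[, 1:2, drop = FALSE]
    pa <- t(xz[, seq_len(tbins), drop = FALSE]) %*% w
    pb <- t(xz[, tbins + seq_len(tbins), drop = FALSE]) %*% w
    list(pa = pa, pb = pb, dist = abs(pa[, 1L] - pb[, 1L]))
  }
  emp <- run_once(mat_a, mat_b)
  null_d <- with_seed(seed, {
    out <- matrix(NA_real_, n_null, tbins)
    x <- cbind(mat_a, mat_b)
    for (i in seq_len(n_null)) {
      xr <- t(vapply(seq_len(nrow(x)), function(j)
        circ_shift(x[j, ], sample.int(ncol(x), 1L)),
        numeric(ncol(x))))
      out[i, ] <- run_once(xr[, seq_len(tbins), drop = FALSE],
                           xr[, tbins + seq_len(tbins),
                              drop = FALSE])$dist
    }
    out
  })
  if (n_null >= 1 / alpha) {
    thresh <- apply(null_d, 2L, stats::quantile, probs = 1 - alpha)
    eff_alpha <- alpha
  } else {
    thresh <- apply(null_d, 2L, max)
    eff_alpha <- 1 / (n_null + 1)
  }
  mask <- significance_mask(emp$dist > thresh, alpha = eff_alpha,
                            min_run = min_run, n_resamples = n_null)
  list(projection_a = emp$pa, projection_b = emp$pb, distance = emp$dist,
       null_max = thresh, mask = mask, effective_alpha = eff_alpha)
}

#' Permutation test on two groups of time series
#'
#' Per time bin, the observed absolute difference of group means is compared
#' with the distribution obtained by re-randomizing neurons between the two
#' groups; a bin is significant when the fraction of permutations with a
#' larger-or-equal absolute difference is below \code{alpha}, and
#' significant bins must come in runs of at least \code{min_run}.
#'
#' @param group_a,group_b neurons x bins matrices (same bin count).
#' @param n_perm number of permutations.
#' @param alpha per-bin alpha level.
#' @param min_run minimum consecutive significant bins.
#' @param seed integer seed.
#' @param strict use strict \code{p < alpha} (default); with
#'   \code{strict = FALSE} bins at the permutation floor also pass.
#' @return a \code{\link{significance_mask}} with an extra \code{p} field of
#'   per-bin permutation p-values.
#' @export
permutation_timeseries_test <- function(group_a, group_b, n_perm = 1000L,
                                        alpha = 0.001, min_run = 10L,
                                        seed = 1L, strict = TRUE) {
  a <- as.matrix(group_a)
  b <- as.matrix(group_b)
  stopifnot(ncol(a) == ncol(b))
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need at least 2 neurons per group", call. = FALSE)
  if (n_perm < 1 / alpha)
    warning("n_perm < 1/alpha: the permutation p-value floor 1/n_perm ",
            "cannot fall below alpha except at exactly zero exceedances",
            call. = FALSE)
  x <- rbind(a, b)
  na <- nrow(a)
  nb <- nrow(b)
  emp <- abs(colMeans(a) - colMeans(b))
  p <- with_seed(seed, {
    w <- matrix(-1 / nb, n_perm, na + nb)
    for (i in seq_len(n_perm))
      w[i, sample.int(na + nb, na)] <- 1 / na
    diffs <- abs(w %*% x)
    (colSums(diffs >= rep(emp, each = n_perm))) / n_perm
  })
  sig <- if (strict) p < alpha else p <= alpha
  m <- significance_mask(sig, alpha = alpha, min_run = min_run,
                         n_resamples = n_perm)
  m$p <- p
  m
}

#' Bootstrap test of a difference array against zero
#'
#' Resamples neurons with replacement, recomputes the per-bin mean
#' difference \code{n_boot} times, and builds a two-sided percentile CI at
#' level \code{1 - alpha}; bins whose CI excludes zero (in runs of at least
#' \code{min_run}) are significant.
#'
#' @param diff neurons x bins matrix of per-neuron differences (e.g. risky
#'   minus safe activity).
#' @param n_boot bootstrap iterations.
#' @param alpha two-sided CI alpha.
#' @param min_run minimum consecutive significant bins.
#' @param seed integer seed.
#' @return a \code{\link{significance_mask}} with extra fields \code{lower}
#'   and \code{upper} (per-bin CI bounds).
#' @export
bootstrap_diff_from_zero <- function(diff, n_boot = 1000L, alpha = 1e-4,
                                     min_run = 10L, seed = 1L) {
  x <- as.matrix(diff)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 neurons", call. = FALSE)
  if (n_boot < 1 / alpha)
    warning("n_boot < 1/alpha: percentile CI at this alpha is the ",
            "bootstrap extreme, a coarser bound than requested",
            call. = FALSE)
  bm <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot)
    cnt <- matrix(0, n_boot, n)
    for (i in seq_len(n_boot)) {
      tb <- tabulate(idx[i, ], nbins = n)
      cnt[i, ] <- tb / n
    }
    cnt %*% x
  })
  lower <- apply(bm, 2L, stats::quantile, probs = alpha / 2)
  upper <- apply(bm, 2L, stats::quantile, probs = 1 - alpha / 2)
  m <- significance_mask(lower > 0 | upper < 0, alpha = alpha,
                         min_run = min_run, n_resamples = n_boot)
  m$lower <- lower
  m$upper <- upper
  m
}
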