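#' Shuffle-null identification of an event-encoding ensemble
#'
#' For each neuron, the empirical statistic is the mean (across events) of
#' its per-trial z-scored epoch-window mean. A null distribution is built by
#' shuffling each (neuron, event) slice in time -- by default an independent
#' uniform circular shift, which preserves the trace's autocorrelation and so
#' yields a conservative null -- and recomputing the statistic
#' \code{n_shuffle} times. A neuron is an ensemble member when its empirical
#' statistic exceeds the null mean by \code{k_sd} null SDs *and* the response
#' is positive-going (fluorescence decay makes negative deflections hard to
#' interpret, so only increases count).
#'
#' The null SD is the SD of the shuffle statistics, not of raw bins. With
#' fewer than \code{min_events} events the category is marked not evaluable
#' rather than absent.
#'
#' @param tensor a \code{peri_event_tensor} (z-scored per trial; a raw tensor
#'   is z-scored internally).
#' @param epoch an \code{\link{epoch_window}} within the tensor window.
#' @param n_shuffle number of shuffles.
#' @param k_sd membership threshold in null SD units.
#' @param seed integer seed.
#' @param min_events minimum events for the category to be evaluable.
#' @param shuffle "circular" (uniform circular shift per slice) or "permute"
#'   (full within-slice permutation).
#' @return an object of class \code{ensemble_assignment}: data frame per
#'   neuron with \code{neuron}, \code{empirical}, \code{null_mean},
#'   \code{null_sd}, \code{member}, \code{evaluable}; attributes carry the
#'   epoch, parameters and event count.
#' @export
identify_ensemble <- function(tensor, epoch, n_shuffle = 1000L, k_sd = 1.5,
                              seed = 1L, min_events = 5L,
                              shuffle = c("circular", "permute")) {
  shuffle <- match.arg(shuffle)
  if (!tensor$zscored) tensor <- zscore_per_trial(tensor)
  d <- dim(tensor$values)
  n <- d[1L]; n_ev <- d[2L]; n_bins <- d[3L]
  idx <- epoch_bin_indices(tensor, epoch)
  L <- length(idx)
  emp <- rowMeans(epoch_mean(tensor, epoch))
  if (n_ev < min_events) {
    out <- data.frame(neuron = seq_len(n), empirical = emp,
                      null_mean = NA_real_, null_sd = NA_real_,
                      member = NA, evaluable = FALSE)
  } else {
    stats_mat <- with_seed(seed, {
      if (shuffle == "circular") {
        # A circular shift of a slice followed by the fixed epoch mean equals
        # the mean of a circularly wrapped window of the same length at a
        # uniformly random start, so precompute all window-start means once.
        M <- array(NA_real_, dim = c(n, n_ev, n_bins))
        for (e in seq_len(n_ev)) {
          sl <- tensor$values[, e, , drop = TRUE]
          if (n == 1L) sl <- matrix(sl, nrow = 1L)
          M[, e, ] <- t(apply(sl, 1L, circ_window_means, L = L))
        }
        starts <- array(sample.int(n_bins, n * n_ev * n_shuffle,
                                   replace = TRUE),
                        dim = c(n, n_ev, n_shuffle))
        lin <- rep(seq_len(n), times = n_ev * n_shuffle) +
          (rep(rep(seq_len(n_ev), each = n), times = n_shuffle) - 1L) * n +
          (as.vector(starts) - 1L) * (n * n_ev)
        arr <- array(M[lin], dim = c(n, n_ev, n_shuffle))
        colMeans(aperm(arr, c(2L, 1L, 3L)), dims = 1L)  # n x n_shuffle
      } else {
        out <- matrix(NA_real_, n, n_shuffle)
        for (b in seq_len(n_shuffle)) {
          acc <- numeric(n)
          for (e in seq_len(n_ev)) {
            sl <- tensor$values[, e, , drop = TRUE]
            if (n == 1L) sl <- matrix(sl, nrow = 1L)
            perm <- sample.int(n_bins)
            acc <- acc + rowMeans(sl[, perm[idx], drop = FALSE])
          }
          out[, b] <- acc / n_ev
        }
        out
      }
    })
    null_mean <- rowMeans(stats_mat)
    null_sd <- apply(stats_mat, 1L, stats::sd)
    out <- data.frame(neuron = seq_len(n), empirical = emp,
                      null_mean = null_mean, null_sd = null_sd,
                      member = emp > null_mean + k_sd * null_sd & emp > 0,
                      evaluable = TRUE)
  }
  structure(out, class = c("ensemble_assignment", "data.frame"),
            category = epoch$name, k_sd = k_sd, n_shuffle = n_shuffle,
            n_events = n_ev)
}

#' Exclusive ensemble labels across categories
#'
#' A neuron is exclusively responsive to a category when it passes the
#' membership threshold for that category but not for the others; neurons
#' passing several categories are "mixed", neurons passing none are "none".
#'
#' @param assignments named list of \code{ensemble_assignment} objects over
#'   the same neurons (e.g. pre_choice, post_choice_rew, consum).
#' @return character vector of per-neuron labels.
#' @export
exclusive_labels <- function(assignments) {
  ns <- vapply(assignments, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("assignments cover different neuron sets", call. = FALSE)
  mem <- vapply(assignments, function(a) a$member %in% TRUE,
                logical(ns[1L]))
  if (is.null(dim(mem))) mem <- matrix(mem, nrow = 1L)
  k <- rowSums(mem)
  lab <- rep("none", nrow(mem))
  lab[k > 1L] <- "mixed"
  one <- which(k == 1L)
  lab[one] <- colnames(mem)[apply(mem[one, , drop = FALSE], 1L, which)]
  lab
}

#' Sub-sample events to match trial counts
#'
#' When safe-block ensembles are compared with pooled risky-block data the
#' event counts are unbalanced; the larger set is randomly sub-sampled
#' (without replacement, temporal order preserved) to the size of the
#' smaller.
#'
#' @param events_a reference event set (vector or data frame).
#' @param events_b event set to sub-sample; must be at least as large.
#' @param seed integer seed.
#' @return \code{events_b} reduced to \code{length(events_a)} elements.
#' @export
match_trial_counts <- function(events_a, events_b, seed = 1L) {
  n_a <- if (is.data.frame(events_a)) nrow(events_a) else length(events_a)
  n_b <- if (is.data.frame(events_b)) nrow(events_b) else length(events_b)
  if (n_b < n_a)
    stop("events_b is smaller than events_a; sub-sampling direction is the ",
         "caller's responsibility", call. = FALSE)
  keep <- with_seed(seed, sort(sample.int(n_b, n_a)))
  if (is.data.frame(events_b)) events_b[keep, , drop = FALSE]
  else events_b[keep]
}

#' Classify safe-to-risky ensemble dynamics
#'
#' Crosses a category's safe-block and (trial-matched) risky-block
#' memberships into Conserved (member in both), Lost (safe only), New (risky
#' only) and never. Fractions are reported both over all neurons and over
#' safe-identified neurons, the two denominators in common use.
#'
#' @param safe,risky \code{ensemble_assignment} objects for the same neurons
#'   and category.
#' @return an object of class \code{ensemble_dynamics}: list with
#'   \code{per_neuron} (neuron, status), \code{fractions} (over all
#'   neurons) and \code{fractions_of_safe} (lost/conserved over
#'   safe-identified neurons).
#' @export
classify_dynamics <- function(safe, risky) {
  if (nrow(safe) != nrow(risky) || !all(safe$neuron == risky$neuron))
    stop("safe and risky assignments cover different neuron sets",
         call. = FALSE)
  s <- safe$member %in% TRUE
  r <- risky$member %in% TRUE
  status <- ifelse(s & r, "conserved",
                   ifelse(s & !r, "lost",
                          ifelse(!s & r, "new", "never")))
  n <- length(status)
  fr <- c(conserved = sum(status == "conserved") / n,
          lost = sum(status == "lost") / n,
          new = sum(status == "new") / n,
          never = sum(status == "never") / n)
  n_safe <- sum(s)
  fr_safe <- c(conserved = if (n_safe) sum(s & r) / n_safe else NA_real_,
               lost = if (n_safe) sum(s & !r) / n_safe else NA_real_)
  structure(list(per_neuron = data.frame(neuron = safe$neuron,
                                         status = status),
                 fractions = fr, fractions_of_safe = fr_safe),
            class = "ensemble_dynamics")
}

#' @export
print.ensemble_dynamics <- function(x, ...) {
  cat("Ensemble dynamics (fractions of all neurons):\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' K-means clustering of epoch response profiles
#'
#' Clusters neurons by their per-epoch mean responses using correlation
#' distance (1 - Pearson r between row profiles): rows are centered and
#' norm-scaled, Lloyd iterations run from multiple random starts, and the
#' solution with the lowest total within-cluster distance is kept. Empty
#' clusters are re-seeded from the point farthest from its centroid.
#' Constant rows (undefined correlation) are excluded with a warning.
#'
#' @param epoch_means neurons x epochs matrix (typically 3 columns).
#' @param n_clusters number of clusters.
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @param max_iter Lloyd iteration cap.
#' @return integer vector of cluster labels (NA for excluded neurons), with
#'   attribute \code{tot_within} (total within-cluster correlation
#'   distance).
#' @export
kmeans_epoch_clusters <- function(epoch_means, n_clusters = 3L, seed = 1L,
                                  n_restarts = 20L, max_iter = 100L) {
  x <- as.matrix(epoch_means)
  ctr <- x - rowMeans(x)
  nrm <- sqrt(rowSums(ctr^2))
  const <- nrm < .Machine$double.eps^0.5
  if (any(const))
    warning(sum(const), " constant-profile neuron(s) excluded from ",
            "clustering", call. = FALSE)
  u <- ctr[!const, , drop = FALSE] / nrm[!const]
  m <- nrow(u)
  if (m < n_clusters)
    stop("fewer usable neurons than clusters", call. = FALSE)
  labels_all <- rep(NA_integer_, nrow(x))
  if (n_clusters == 1L) {
    labels_all[!const] <- 1L
    attr(labels_all, "tot_within") <- sum(1 - u %*% normalize_row(colMeans(u)))
    return(labels_all)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cent <- u[sample.int(m, n_clusters), , drop = FALSE]
      lab <- integer(m)
      for (it in seq_len(max_iter)) {
        # correlation distance = 1 - u %*% t(cent) for unit rows
        sim <- u %*% t(cent)
        new_lab <- max.col(sim, ties.method = "first")
        for (kk in seq_len(n_clusters)) {
          if (!any(new_lab == kk)) {
            d_own <- 1 - sim[cbind(seq_len(m), new_lab)]
            far <- which.max(d_own)
            new_lab[far] <- kk
          }
        }
        if (identical(new_lab, lab)) break
        lab <- new_lab
        for (kk in seq_len(n_clusters))
          cent[kk, ] <- normalize_row(
            colMeans(u[lab == kk, , drop = FALSE]))
      }
      tw <- sum(1 - (u %*% t(cent))[cbind(seq_len(m), lab)])
      if (is.null(best) || tw < best$tw) best <- list(lab = lab, tw = tw)
    }
  })
  labels_all[!const] <- best$lab
  attr(labels_all, "tot_within") <- best$tw
  labels_all
}

normalize_row <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) return(v)
  v / n
}

#' Compare two proportions
#'
#' Large-sample chi-square test of proportions or two-proportion z-test
#' (pooled SE), two-sided. For a 2x2 table the chi-square statistic equals
#' the squared z statistic.
#'
#' @param x1,n1,x2,n2 successes and totals for the two groups.
#' @param method "chi_square" or "two_proportion_z".
#' @return list with \code{statistic} and \code{p_value}.
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                method = c("chi_square",
                                           "two_proportion_z")) {
  method <- match.arg(method)
  if (any(c(x1, x2) < 0) || x1 > n1 || x2 > n2 || n1 <= 0 || n2 <= 0)
    stop("require 0 <= x <= n and n > 0", call. = FALSE)
  exp_counts <- outer(c(x1 + x2, n1 + n2 - x1 - x2), c(n1, n2)) /
    (n1 + n2)
  if (method == "chi_square" && any(exp_counts < 5))
    warning("chi-square expected count below 5; large-sample p is ",
            "approximate", call. = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  if (method == "two_proportion_z")
    list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
  else
    list(statistic = z^2, p_value = stats::pchisq(z^2, df = 1,
                                                  lower.tail = FALSE))
}
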