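#' Per-block free-choice percentages
#'
#' Percentage of free-choice trials on which each option was selected,
#' computed as 100 * (number of choices) / (free trials per block).
#'
#' @param session a \code{\link{behavioral_session}}.
#' @return data frame with one row per block: \code{block}, \code{n_free},
#'   \code{large_pct}, \code{small_pct}. Blocks with no free trials yield NA.
#' @export
choice_percentages <- function(session) {
  comp <- completed_trials(session)
  free <- comp[comp$kind == "free", , drop = FALSE]
  blocks <- sort(unique(session$schedule$block))
  out <- lapply(blocks, function(b) {
    fb <- free[free$block == b, , drop = FALSE]
    n <- nrow(fb)
    if (n == 0L)
      return(data.frame(block = b, n_free = 0L, large_pct = NA_real_,
                        small_pct = NA_real_))
    data.frame(block = b, n_free = n,
               large_pct = 100 * sum(fb$choice == "large") / n,
               small_pct = 100 * sum(fb$choice == "small") / n)
  })
  do.call(rbind, out)
}

#' Per-trial latencies
#'
#' Choice latency (initiation to choice), reward-collection latency (choice
#' to collection), consumption duration (collection to consumption end), and
#' initiation latency (interval from a completed trial's consumption end to
#' the initiation of the next trial). Omitted presentations yield NA.
#'
#' @param session a \code{\link{behavioral_session}}.
#' @return data frame with one row per trial presentation: \code{block},
#'   \code{kind}, \code{choice}, \code{choice_latency_s},
#'   \code{collection_latency_s}, \code{consumption_s},
#'   \code{initiation_latency_s} (NA for the final completed trial).
#' @export
latencies <- function(session) {
  tr <- session$trials
  out <- data.frame(block = tr$block, kind = tr$kind, choice = tr$choice,
                    choice_latency_s = tr$t_choice - tr$t_init,
                    collection_latency_s = tr$t_collect - tr$t_choice,
                    consumption_s = tr$t_consume_end - tr$t_collect,
                    initiation_latency_s = NA_real_)
  neg <- which(out$choice_latency_s < 0 | out$collection_latency_s < 0 |
                 out$consumption_s < 0)
  if (length(neg))
    stop("negative latency (non-monotone timestamps) in trial(s): ",
         paste(utils::head(neg, 5L), collapse = ", "), call. = FALSE)
  idx_comp <- which(tr$choice != "omission")
  if (length(idx_comp) > 1L) {
    for (k in seq_len(length(idx_comp) - 1L)) {
      i <- idx_comp[k]
      j <- idx_comp[k + 1L]
      out$initiation_latency_s[i] <- tr$t_init[j] - tr$t_consume_end[i]
    }
  }
  out
}

#' Bootstrap latency flags against the safe block
#'
#' Flags trials whose latency exceeds the upper bound of a percentile
#' confidence interval built from 1000 bootstrapped means of the safe-block
#' latencies (two-sided level 1 - alpha; flags are raised on upper-bound
#' exceedance only, since risk slows responding). This mirrors the
#' mean-referenced bootstrap used for group latency curves; because a single
#' trial is compared against the CI of a mean, the rule is deliberately
#' liberal for individual trials.
#'
#' @param trial_latencies numeric vector of per-trial latencies, in trial
#'   order (typically trial means across subjects).
#' @param safe_idx indices of the safe-block trials (default 1:30).
#' @param n_boot number of bootstrap resamples.
#' @param alpha two-sided CI alpha.
#' @param seed integer seed.
#' @return logical vector, one flag per trial (NA latencies yield FALSE).
#' @export
latency_bootstrap_flags <- function(trial_latencies, safe_idx = 1:30,
                                    n_boot = 1000L, alpha = 0.001,
                                    seed = 1L) {
  safe <- trial_latencies[safe_idx]
  safe <- safe[!is.na(safe)]
  if (length(safe) < 2L)
    stop("safe block must contain at least 2 non-missing latencies",
         call. = FALSE)
  with_seed(seed, {
    idx <- matrix(sample.int(length(safe), n_boot * length(safe),
                             replace = TRUE), nrow = n_boot)
    boot_means <- rowMeans(matrix(safe[idx], nrow = n_boot))
    upper <- stats::quantile(boot_means, 1 - alpha / 2, names = FALSE)
    flags <- !is.na(trial_latencies) & trial_latencies > upper
    flags
  })
}

#' Per-block abort counts by target
#'
#' @param session a \code{\link{behavioral_session}}.
#' @return data frame: \code{block}, \code{large}, \code{small}.
#' @export
abort_counts <- function(session) {
  ab <- session$aborts
  if (nrow(ab) && !all(ab$target %in% c("large", "small")))
    stop("unknown abort target label: ",
         paste(setdiff(unique(ab$target), c("large", "small")),
               collapse = ", "), call. = FALSE)
  blocks <- sort(unique(session$schedule$block))
  ab_block <- session$trials$block[ab$trial_index]
  out <- lapply(blocks, function(b) {
    sel <- which(ab_block == b)
    data.frame(block = b,
               large = sum(ab$target[sel] == "large"),
               small = sum(ab$target[sel] == "small"))
  })
  do.call(rbind, out)
}

#' Punishment-to-abort contingency
#'
#' For each punished trial, asks whether the next behavioral event was an
#' abort or a completed choice, and counts the two outcomes. Punished trials
#' with no subsequent event are skipped.
#'
#' @param session a \code{\link{behavioral_session}}.
#' @return list with \code{followed_by_abort} and \code{followed_by_choice}
#'   counts and \code{n_punished}.
#' @export
punishment_abort_contingency <- function(session) {
  tr <- session$trials
  punished_idx <- which(tr$punished)
  if (!length(punished_idx))
    stop("session contains no punished trials", call. = FALSE)
  comp_idx <- which(tr$choice != "omission")
  n_ab <- 0L
  n_ch <- 0L
  for (i in punished_idx) {
    nxt <- comp_idx[comp_idx > i]
    if (!length(nxt)) next
    j <- nxt[1L]
    had_abort <- any(session$aborts$trial_index == j)
    if (had_abort) n_ab <- n_ab + 1L else n_ch <- n_ch + 1L
  }
  list(followed_by_abort = n_ab, followed_by_choice = n_ch,
       n_punished = length(punished_idx))
}

#' Savitzky-Golay smoothing of a pose track
#'
#' Polynomial smoothing (order 3, 25-frame window by default) applied to each
#' coordinate, as used on markerless pose tracks before kinematic analysis.
#'
#' @param track data frame with columns \code{frame}, \code{x}, \code{y}.
#' @param order polynomial order.
#' @param window window length in frames (odd).
#' @return the track with smoothed \code{x}, \code{y}.
#' @export
smooth_track <- function(track, order = 3L, window = 25L) {
  if (nrow(track) < window)
    stop("track shorter than the smoothing window (", window, " frames)",
         call. = FALSE)
  track$x <- as.numeric(signal::sgolayfilt(track$x, p = order, n = window))
  track$y <- as.numeric(signal::sgolayfilt(track$y, p = order, n = window))
  track
}

#' Path length of a pose track over a frame window
#'
#' Sum of Euclidean distances between consecutive samples.
#'
#' @param track data frame with columns \code{frame}, \code{x}, \code{y}.
#' @param frame_start,frame_end inclusive frame window (defaults: whole
#'   track).
#' @return total distance in track units.
#' @export
path_length <- function(track, frame_start = -Inf, frame_end = Inf) {
  w <- track[track$frame >= frame_start & track$frame <= frame_end, ,
             drop = FALSE]
  if (nrow(w) < 2L)
    stop("path window must contain at least 2 frames", call. = FALSE)
  sum(sqrt(diff(w$x)^2 + diff(w$y)^2))
}
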