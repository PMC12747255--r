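#' Control-channel regression and event-window dF
#'
#' For each event, both channels are extracted over a peri-event window
#' (default 10 s, centered on the event), the control channel is scaled onto
#' the signal channel by ordinary least squares within the window, and the
#' event-related change in fluorescence is the residual dF = signal - fitted
#' control. dF is then z-normalized using the event window's own mean and
#' SD. Whole-session fitting is available as an option; a degenerate
#' (constant) control within a window falls back to mean-offset subtraction
#' with a warning.
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param event_window_s total window length around each event (s).
#' @param event_label which labeled events to extract (default "choice").
#' @param scope fit the control per event window (default) or once for the
#'   whole session.
#' @param normalize z-normalize over the full window (default) or a
#'   pre-event baseline (the window's first half).
#' @return an object of class \code{event_dff}: list with \code{z}
#'   (events x bins z-normalized dF), \code{offsets_s}, \code{events}
#'   (metadata rows for the retained events), \code{window_s}.
#' @export
fit_control_and_dff <- function(rec, event_window_s = 10,
                                event_label = "choice",
                                scope = c("event", "session"),
                                normalize = c("window", "baseline")) {
  scope <- match.arg(scope)
  normalize <- match.arg(normalize)
  ev <- rec$events[rec$events$label %in% event_label, , drop = FALSE]
  if (!nrow(ev)) stop("no events with label ", event_label, call. = FALSE)
  rate <- rec$rate_hz
  half <- event_window_s / 2
  n_bins <- round(event_window_s * rate)
  n_samp <- length(rec$signal)
  centers <- round(ev$time * rate) + 1L
  start <- centers - round(half * rate)
  ok <- start >= 1L & (start + n_bins - 1L) <= n_samp
  if (!any(ok)) stop("no event window lies inside the recording",
                     call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: window outside the recording",
            call. = FALSE)
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  if (scope == "session") {
    fit <- stats::lm.fit(cbind(1, rec$control), rec$signal)
    dff_all <- rec$signal - cbind(1, rec$control) %*% fit$coefficients
  }
  z <- matrix(NA_real_, nrow(ev), n_bins)
  for (i in seq_len(nrow(ev))) {
    idx <- start[i]:(start[i] + n_bins - 1L)
    if (scope == "event") {
      s <- rec$signal[idx]
      c0 <- rec$control[idx]
      if (stats::sd(c0) < .Machine$double.eps^0.5) {
        warning("constant control channel in event window ", i,
                "; using mean-offset subtraction", call. = FALSE)
        dff <- s - mean(s)
      } else {
        co <- stats::lm.fit(cbind(1, c0), s)$coefficients
        dff <- s - as.numeric(cbind(1, c0) %*% co)
      }
    } else dff <- dff_all[idx]
    norm_idx <- if (normalize == "window") seq_len(n_bins)
      else seq_len(n_bins %/% 2L)
    mu <- mean(dff[norm_idx])
    sd0 <- stats::sd(dff[norm_idx])
    if (sd0 < .Machine$double.eps^0.5) sd0 <- 1
    z[i, ] <- (dff - mu) / sd0
  }
  structure(list(z = z,
                 offsets_s = -half + (seq_len(n_bins) - 0.5) / rate,
                 events = ev, window_s = event_window_s),
            class = "event_dff")
}

#' @export
print.event_dff <- function(x, ...) {
  cat("Event dF/F:", nrow(x$z), "events x", ncol(x$z), "bins (",
      x$window_s, "s window)\n")
  invisible(x)
}

#' Bootstrap confidence band on the event-mean dF trace
#'
#' Resamples events with replacement, recomputes the per-bin mean
#' \code{n_boot} times, and reports the percentile confidence band; bins
#' whose band excludes zero are significant.
#'
#' @param dff an \code{event_dff}.
#' @param n_boot bootstrap iterations.
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{lower}, \code{upper},
#'   \code{significant} (per-bin logical) and \code{offsets_s}.
#' @export
bootstrap_event_ci <- function(dff, n_boot = 1000L, level = 0.95,
                               seed = 1L) {
  z <- dff$z
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 events", call. = FALSE)
  bm <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot)
    cnt <- matrix(0, n_boot, n)
    for (i in seq_len(n_boot)) cnt[i, ] <- tabulate(idx[i, ], n) / n
    cnt %*% z
  })
  a <- (1 - level) / 2
  lower <- apply(bm, 2L, stats::quantile, probs = a)
  upper <- apply(bm, 2L, stats::quantile, probs = 1 - a)
  list(mean = colMeans(z), lower = lower, upper = upper,
       significant = lower > 0 | upper < 0, offsets_s = dff$offsets_s)
}

#' Pre-choice AUC contrast between safe and risky blocks
#'
#' Per subject, the trapezoidal area under the z-normalized dF curve over
#' the pre-choice window (-4 to 0 s by default) is averaged over safe-block
#' (block 1) and risky-block (blocks >= 2) events; the per-subject pairs are
#' compared with a paired t-test.
#'
#' @param dff_list list of \code{event_dff} objects, one per subject, whose
#'   event metadata carries \code{block}.
#' @param window AUC window relative to the event (s).
#' @return list with \code{per_subject} (data frame: auc_safe, auc_risky),
#'   \code{t_statistic}, \code{p_value}.
#' @export
prechoice_auc_contrast <- function(dff_list, window = c(-4, 0)) {
  if (inherits(dff_list, "event_dff")) dff_list <- list(dff_list)
  per <- lapply(dff_list, function(d) {
    sel <- d$offsets_s >= window[1L] & d$offsets_s <= window[2L]
    if (!any(sel)) stop("AUC window outside the event window",
                        call. = FALSE)
    tts <- d$offsets_s[sel]
    auc <- apply(d$z[, sel, drop = FALSE], 1L, function(y) trapz(tts, y))
    blk <- d$events$block
    if (!any(blk == 1L) || !any(blk >= 2L))
      stop("both safe and risky blocks must be present", call. = FALSE)
    c(auc_safe = mean(auc[blk == 1L]), auc_risky = mean(auc[blk >= 2L]))
  })
  ps <- as.data.frame(do.call(rbind, per))
  if (nrow(ps) >= 2L) {
    tt <- paired_block_t(ps$auc_safe, ps$auc_risky)
    list(per_subject = ps, t_statistic = tt$t_statistic,
         p_value = tt$p_value)
  } else list(per_subject = ps, t_statistic = NA_real_,
              p_value = NA_real_)
}
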