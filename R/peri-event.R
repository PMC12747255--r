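#' Epoch sub-window definitions
#'
#' Named offset windows relative to an anchor event, matching the
#' event-specific sub-windows used throughout the analyses: pre-choice -4 to
#' 0 s relative to choice; post-choice (rewarded or punished) 0 to +2 s
#' relative to choice; consumption +1 to +3 s relative to reward collection;
#' abort 0 to +2 s relative to abort onset.
#'
#' @param name window name.
#' @param start_s,end_s offsets from the anchor (s), \code{start_s < end_s}.
#' @return an object of class \code{epoch_window}.
#' @export
epoch_window <- function(name, start_s, end_s) {
  if (!(start_s < end_s))
    stop("epoch window requires start_s < end_s", call. = FALSE)
  structure(list(name = name, start_s = start_s, end_s = end_s),
            class = "epoch_window")
}

#' @rdname epoch_window
#' @param category one of the standard category names.
#' @export
standard_epoch <- function(category = c("pre_choice", "post_choice_rew",
                                        "post_choice_pun", "consum",
                                        "abort")) {
  category <- match.arg(category)
  w <- switch(category,
    pre_choice = c(-4, 0),
    post_choice_rew = c(0, 2),
    post_choice_pun = c(0, 2),
    consum = c(1, 3),
    abort = c(0, 2))
  epoch_window(category, w[1L], w[2L])
}

#' Extract a peri-event tensor from a trace matrix
#'
#' Slices each neuron's trace around each event time, aligning the event to
#' the nearest sample and using half-open bins [t, t + bin). Events whose
#' window would fall outside the recording are dropped with a warning.
#'
#' @param traces a \code{\link{trace_matrix}}.
#' @param event_times event anchor times (s from recording start).
#' @param window c(start, end) offsets around each event (s); default
#'   (-10, 10).
#' @param event_meta optional data frame of per-event metadata (block, choice
#'   type, punished); rows of dropped events are removed.
#' @return an object of class \code{peri_event_tensor}: list with
#'   \code{values} (neurons x events x bins array), \code{bin_s},
#'   \code{offsets_s} (bin start offsets), \code{events} (metadata),
#'   \code{zscored} flag.
#' @export
extract_peri_event <- function(traces, event_times, window = c(-10, 10),
                               event_meta = NULL) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (!length(event_times)) stop("no events supplied", call. = FALSE)
  rate <- traces$rate_hz
  n_samp <- ncol(traces$values)
  i0 <- round(window[1L] * rate)
  n_bins <- round((window[2L] - window[1L]) * rate)
  centers <- round(event_times * rate) + 1L
  start <- centers + i0
  end <- start + n_bins - 1L
  ok <- start >= 1L & end <= n_samp
  if (!any(ok))
    stop("all events fall too close to the recording edges", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: window outside the recording",
            call. = FALSE)
  start <- start[ok]
  n_ev <- length(start)
  n_neur <- nrow(traces$values)
  vals <- array(NA_real_, dim = c(n_neur, n_ev, n_bins))
  for (e in seq_len(n_ev))
    vals[, e, ] <- traces$values[, start[e]:(start[e] + n_bins - 1L)]
  meta <- if (!is.null(event_meta)) event_meta[ok, , drop = FALSE] else
    data.frame(row.names = seq_len(n_ev))
  meta$time <- event_times[ok]
  structure(list(values = vals, bin_s = 1 / rate,
                 offsets_s = window[1L] + (seq_len(n_bins) - 1L) / rate,
                 events = meta, zscored = FALSE,
                 constant = matrix(FALSE, n_neur, n_ev)),
            class = "peri_event_tensor")
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("Peri-event tensor:", d[1L], "neurons x", d[2L], "events x", d[3L],
      "bins (", x$bin_s, "s bins,",
      if (x$zscored) "z-scored" else "raw", ")\n")
  invisible(x)
}

#' Z-score a peri-event tensor per trial
#'
#' For each (neuron, event) slice, subtracts the window mean and divides by
#' the window SD (population SD, ddof 0). Constant slices map to all zeros
#' and are flagged. Idempotent to numerical tolerance.
#'
#' @param tensor a raw \code{peri_event_tensor}.
#' @return the tensor with z-scored values and \code{zscored = TRUE}.
#' @export
zscore_per_trial <- function(tensor) {
  v <- tensor$values
  d <- dim(v)
  if (d[3L] < 2L) stop("z-scoring needs at least 2 bins", call. = FALSE)
  m <- apply(v, c(1L, 2L), mean)
  s <- sqrt(apply(v, c(1L, 2L), function(x) mean((x - mean(x))^2)))
  const <- s < .Machine$double.eps^0.5
  s[const] <- 1
  tensor$values <- (v - array(m, d)) / array(s, d)
  tensor$values[array(const, d)] <- 0
  tensor$constant <- const
  tensor$zscored <- TRUE
  tensor
}

epoch_bin_indices <- function(tensor, epoch) {
  idx <- which(tensor$offsets_s >= epoch$start_s - 1e-9 &
                 tensor$offsets_s < epoch$end_s - 1e-9)
  if (!length(idx) ||
      epoch$start_s < min(tensor$offsets_s) - 1e-9 ||
      epoch$end_s > max(tensor$offsets_s) + tensor$bin_s + 1e-9)
    stop("epoch window (", epoch$start_s, ", ", epoch$end_s,
         ") outside the tensor window", call. = FALSE)
  idx
}

#' Epoch mean per neuron per event
#'
#' Arithmetic mean of the tensor over the epoch's bins.
#'
#' @param tensor a \code{peri_event_tensor}.
#' @param epoch an \code{\link{epoch_window}} contained in the tensor window.
#' @return neurons x events matrix.
#' @export
epoch_mean <- function(tensor, epoch) {
  idx <- epoch_bin_indices(tensor, epoch)
  apply(tensor$values[, , idx, drop = FALSE], c(1L, 2L), mean)
}
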