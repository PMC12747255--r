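#' Fluorescence trace matrix
#'
#' A neurons x samples matrix of dF/F traces at a uniform sampling rate.
#'
#' @param values numeric matrix, neurons in rows.
#' @param rate_hz sampling rate (Hz), default 20.
#' @return an object of class \code{trace_matrix}.
#' @export
trace_matrix <- function(values, rate_hz = 20) {
  stopifnot(is.matrix(values), rate_hz > 0)
  structure(list(values = values, rate_hz = rate_hz),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("Trace matrix:", nrow(x$values), "neurons x", ncol(x$values),
      "samples @", x$rate_hz, "Hz (",
      round(ncol(x$values) / x$rate_hz, 1), "s )\n")
  invisible(x)
}

#' Neuron population specification for the trace simulator
#'
#' Describes a ground-truth-labeled population. Each neuron is assigned a
#' remapping status -- \code{conserved} (event-locked in all blocks),
#' \code{lost} (block 1 only), \code{new} (blocks 2-3 only) or \code{never}
#' (pure noise) -- with exact rounded counts from \code{remap_fractions}.
#' Event-locked neurons draw their encoded event category from
#' \code{ensemble_fractions} (relative weights over the named categories;
#' the \code{none} entry is implied by \code{remap_fractions}). Transients
#' are double-exponential calcium kernels with trial-varying amplitude;
#' pre-choice amplitudes are coupled to choice latency at a target Pearson r.
#'
#' Default remap fractions follow the observed safe-to-risky reorganization
#' (about 12 percent Conserved, 26 percent Lost, 20 percent New of all
#' imaged neurons).
#'
#' @param n_neurons number of neurons.
#' @param ensemble_fractions named weights over event categories
#'   (\code{pre_choice}, \code{post_choice_rew}, \code{post_choice_pun},
#'   \code{consum}, \code{abort}).
#' @param remap_fractions named fractions of all neurons that are
#'   \code{conserved}, \code{lost}, \code{new}.
#' @param transient_amplitude_mean,transient_amplitude_sd dF/F transient
#'   amplitude mean and trial-to-trial SD (amplitudes truncated at 0).
#' @param amplitude_heterogeneity_sdlog lognormal SD of the per-neuron
#'   amplitude scale, capturing the cell-to-cell response-size variability
#'   seen in calcium imaging; 0 makes all neurons share one mean amplitude.
#' @param kernel_rise_s,kernel_decay_s calcium kernel time constants (s).
#' @param noise_sd additive Gaussian noise SD (dF/F units).
#' @param latency_coupling_r target correlation between pre-choice transient
#'   amplitude and choice latency (negative: slower trials, weaker
#'   pre-choice activity).
#' @param overlap_fraction fraction of event-locked neurons carrying a second
#'   event category (mixed identity).
#' @param drift_amplitude amplitude of slow sinusoidal baseline drift;
#'   default 10 percent of the mean transient amplitude.
#' @return an object of class \code{neuron_spec}.
#' @export
neuron_spec <- function(n_neurons = 300L,
                        ensemble_fractions = c(pre_choice = 0.30,
                                               post_choice_rew = 0.25,
                                               post_choice_pun = 0.15,
                                               consum = 0.25,
                                               abort = 0.05),
                        remap_fractions = c(conserved = 0.12,
                                            lost = 0.26,
                                            new = 0.20),
                        transient_amplitude_mean = 1,
                        transient_amplitude_sd = 0.2,
                        kernel_rise_s = 0.2,
                        kernel_decay_s = 1,
                        noise_sd = 0.1,
                        latency_coupling_r = -0.3,
                        amplitude_heterogeneity_sdlog = 0.4,
                        overlap_fraction = 0,
                        drift_amplitude = NULL) {
  if (sum(remap_fractions) > 1 + 1e-9)
    stop("remap_fractions must sum to at most 1", call. = FALSE)
  if (any(remap_fractions < 0) || any(ensemble_fractions < 0))
    stop("fractions must be non-negative", call. = FALSE)
  if (kernel_rise_s <= 0 || kernel_decay_s <= 0)
    stop("kernel time constants must be positive", call. = FALSE)
  structure(list(
    n_neurons = as.integer(n_neurons),
    ensemble_fractions = ensemble_fractions,
    remap_fractions = remap_fractions,
    transient_amplitude_mean = transient_amplitude_mean,
    transient_amplitude_sd = transient_amplitude_sd,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    noise_sd = noise_sd,
    latency_coupling_r = latency_coupling_r,
    amplitude_heterogeneity_sdlog = amplitude_heterogeneity_sdlog,
    overlap_fraction = overlap_fraction,
    drift_amplitude = drift_amplitude %||% 0.1 * transient_amplitude_mean
  ), class = "neuron_spec")
}

# Double-exponential calcium kernel, peak-normalized to 1.
calcium_kernel <- function(rise_s, decay_s, rate_hz) {
  t <- seq(0, decay_s * 6 + rise_s * 3, by = 1 / rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# Onset jitter: uniformly within the first half of the category's epoch
# window, so epoch means stay robust to alignment choices.
category_onset_range <- function(category) {
  w <- switch(category,
    pre_choice = c(-4, 0),
    post_choice_rew = c(0, 2),
    post_choice_pun = c(0, 2),
    consum = c(1, 3),
    abort = c(0, 2),
    stop("unknown category: ", category, call. = FALSE))
  c(w[1L], (w[1L] + w[2L]) / 2)
}

# Anchor times for a category within a session (completed trials only).
category_event_times <- function(session, category) {
  tr <- completed_trials(session)
  switch(category,
    pre_choice = tr$t_choice,
    post_choice_rew = tr$t_choice[!tr$punished],
    post_choice_pun = tr$t_choice[tr$punished],
    consum = tr$t_collect,
    abort = session$aborts$t_abort,
    stop("unknown category: ", category, call. = FALSE))
}

category_event_blocks <- function(session, category) {
  tr <- completed_trials(session)
  switch(category,
    pre_choice = tr$block,
    post_choice_rew = tr$block[!tr$punished],
    post_choice_pun = tr$block[tr$punished],
    consum = tr$block,
    abort = session$trials$block[session$aborts$trial_index],
    stop("unknown category: ", category, call. = FALSE))
}

#' Simulate ground-truth-labeled calcium traces for a session
#'
#' Event-locked neurons receive one double-exponential transient per relevant
#' event, onset jittered within the first half of the category's epoch
#' window, amplitude Normal(mean, SD) truncated at 0. Lost neurons emit only
#' in block 1, New neurons only in blocks 2-3, Conserved in all blocks.
#' Pre-choice amplitudes are coupled to choice latencies at the configured
#' correlation. All neurons receive additive Gaussian noise plus slow
#' two-sinusoid baseline drift.
#'
#' @param session a \code{\link{behavioral_session}}.
#' @param spec a \code{\link{neuron_spec}}.
#' @param rate_hz sampling rate (Hz).
#' @param seed integer seed.
#' @return list with \code{traces} (a \code{\link{trace_matrix}}) and
#'   \code{truth}, a data frame per neuron: \code{neuron}, \code{status}
#'   (conserved/lost/new/never), \code{category} (or "none"),
#'   \code{category2} (optional second identity), \code{safe_label},
#'   \code{risky_label}.
#' @export
simulate_traces <- function(session, spec = neuron_spec(), rate_hz = 20,
                            seed = 1L) {
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  tr <- completed_trials(session)
  t_end <- max(tr$t_consume_end, session$aborts$t_abort, 0) + 12
  n_samp <- ceiling(t_end * rate_hz)
  n <- spec$n_neurons
  with_seed(seed, {
    # exact rounded status counts, randomized assignment
    counts <- round(n * spec$remap_fractions)
    status <- rep("never", n)
    pool <- sample.int(n)
    k <- 0L
    for (s in names(counts)) {
      if (counts[[s]] > 0L)
        status[pool[(k + 1L):(k + counts[[s]])]] <- s
      k <- k + counts[[s]]
    }
    active <- status != "never"
    cat_w <- spec$ensemble_fractions / sum(spec$ensemble_fractions)
    category <- rep("none", n)
    category[active] <- sample(names(cat_w), sum(active), replace = TRUE,
                               prob = cat_w)
    category2 <- rep(NA_character_, n)
    if (spec$overlap_fraction > 0) {
      cand <- which(active & stats::runif(n) < spec$overlap_fraction)
      for (i in cand) {
        alt <- setdiff(names(cat_w), category[i])
        category2[i] <- sample(alt, 1L,
                               prob = cat_w[alt] / sum(cat_w[alt]))
      }
    }
    kern <- calcium_kernel(spec$kernel_rise_s, spec$kernel_decay_s, rate_hz)
    lk <- length(kern)
    # per-neuron response-size scale (cell-to-cell heterogeneity)
    amp_scale <- stats::rlnorm(n, 0, spec$amplitude_heterogeneity_sdlog)
    # standardized choice latencies keyed by choice time, for amplitude
    # coupling of pre-choice neurons
    lat <- tr$t_choice - tr$t_init
    zlat <- as.numeric(scale(lat))
    zlat[!is.finite(zlat)] <- 0
    rho <- spec$latency_coupling_r
    values <- matrix(0, n, n_samp)
    tt <- seq(0, by = 1 / rate_hz, length.out = n_samp)
    for (i in seq_len(n)) {
      x <- stats::rnorm(n_samp, 0, spec$noise_sd)
      # slow drift: 2 sinusoids, random period (50-200 s) and phase
      for (j in 1:2) {
        f <- stats::runif(1, 1 / 200, 1 / 50)
        x <- x + (spec$drift_amplitude / 2) *
          sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      }
      cats <- c(category[i], category2[i])
      cats <- cats[!is.na(cats) & cats != "none"]
      for (cc in cats) {
        ev_t <- category_event_times(session, cc)
        ev_b <- category_event_blocks(session, cc)
        keep <- switch(status[i],
                       conserved = rep(TRUE, length(ev_t)),
                       lost = ev_b == 1L,
                       new = ev_b >= 2L,
                       rep(FALSE, length(ev_t)))
        ev_t_i <- ev_t[keep]
        if (!length(ev_t_i)) next
        eps <- stats::rnorm(length(ev_t_i))
        if (cc == "pre_choice") {
          zl <- zlat[match(ev_t_i, tr$t_choice)]
          zl[is.na(zl)] <- 0
          amp_z <- rho * zl + sqrt(max(0, 1 - rho^2)) * eps
        } else amp_z <- eps
        amp <- amp_scale[i] * pmax(0, spec$transient_amplitude_mean +
                                     spec$transient_amplitude_sd * amp_z)
        orng <- category_onset_range(cc)
        onset <- ev_t_i + stats::runif(length(ev_t_i), orng[1L], orng[2L])
        for (e in seq_along(onset)) {
          s0 <- round(onset[e] * rate_hz) + 1L
          if (s0 < 1L || s0 > n_samp) next
          s1 <- min(n_samp, s0 + lk - 1L)
          x[s0:s1] <- x[s0:s1] + amp[e] * kern[seq_len(s1 - s0 + 1L)]
        }
      }
      values[i, ] <- x
    }
    truth <- data.frame(
      neuron = seq_len(n), status = status, category = category,
      category2 = category2, amp_scale = amp_scale,
      safe_label = ifelse(status %in% c("conserved", "lost"),
                          category, "none"),
      risky_label = ifelse(status %in% c("conserved", "new"),
                           category, "none"),
      stringsAsFactors = FALSE)
    list(traces = trace_matrix(values, rate_hz), truth = truth)
  })
}
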