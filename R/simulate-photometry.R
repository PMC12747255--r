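#' Two-channel photometry recording
#'
#' Bulk-fluorescence signal (calcium-sensitive channel) and control
#' (calcium-independent channel) series at a uniform rate, with labeled event
#' times.
#'
#' @param signal,control numeric vectors of equal length.
#' @param rate_hz sampling rate (Hz).
#' @param events data frame: \code{time} (s), \code{label} (choice,
#'   collection, punishment), \code{block}, and optionally \code{punished}.
#' @return an object of class \code{photometry_recording}.
#' @export
photometry_recording <- function(signal, control, rate_hz, events) {
  if (length(signal) != length(control))
    stop("signal and control channels must have equal length", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  structure(list(signal = signal, control = control, rate_hz = rate_hz,
                 events = events),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat("Photometry recording:", length(x$signal), "samples @", x$rate_hz,
      "Hz,", nrow(x$events), "events\n")
  invisible(x)
}

#' Photometry simulation parameters
#'
#' @param rate_hz sampling rate of the demodulated series (Hz).
#' @param artifact_amplitude amplitude of the motion/bleaching artifact
#'   shared by both channels.
#' @param artifact_gain multiplier applied to the shared artifact in the
#'   signal channel.
#' @param control_offset additive offset of the control channel.
#' @param noise_sd per-channel measurement noise SD.
#' @param prechoice_amplitude amplitude of the pre-choice calcium component.
#' @param prechoice_attenuation multiplier on the pre-choice component in
#'   risky blocks (blocks >= 2).
#' @param punish_amplitude amplitude of the post-choice punishment transient
#'   (the largest task transient).
#' @param reward_amplitude amplitude of the reward-collection transient.
#' @return a list of class \code{photometry_params}.
#' @export
photometry_params <- function(rate_hz = 20, artifact_amplitude = 1,
                              artifact_gain = 0.8, control_offset = 5,
                              noise_sd = 0.05, prechoice_amplitude = 1,
                              prechoice_attenuation = 0.5,
                              punish_amplitude = 3, reward_amplitude = 1) {
  structure(list(rate_hz = rate_hz, artifact_amplitude = artifact_amplitude,
                 artifact_gain = artifact_gain,
                 control_offset = control_offset, noise_sd = noise_sd,
                 prechoice_amplitude = prechoice_amplitude,
                 prechoice_attenuation = prechoice_attenuation,
                 punish_amplitude = punish_amplitude,
                 reward_amplitude = reward_amplitude),
            class = "photometry_params")
}

#' Simulate a two-channel photometry recording for a session
#'
#' The control channel carries a shared slow artifact plus offset and noise;
#' the signal channel carries a scaled copy of the same artifact plus
#' event-locked calcium components and noise. Punished choices carry the
#' largest transients; the pre-choice ramp is attenuated by a configurable
#' factor on risky blocks, giving downstream contrasts a known effect to
#' detect.
#'
#' @param session a \code{\link{behavioral_session}}.
#' @param params a \code{\link{photometry_params}}.
#' @param seed integer seed.
#' @return a \code{\link{photometry_recording}}.
#' @export
simulate_photometry <- function(session, params = photometry_params(),
                                seed = 1L) {
  tr <- completed_trials(session)
  rate <- params$rate_hz
  t_end <- max(tr$t_consume_end) + 12
  n <- ceiling(t_end * rate)
  tt <- seq(0, by = 1 / rate, length.out = n)
  with_seed(seed, {
    artifact <- numeric(n)
    for (j in 1:3) {
      f <- stats::runif(1, 1 / 300, 1 / 40)
      artifact <- artifact + sin(2 * pi * f * tt +
                                   stats::runif(1, 0, 2 * pi))
    }
    artifact <- params$artifact_amplitude * artifact / 3
    kern <- calcium_kernel(0.3, 1.5, rate)
    add_transient <- function(x, t0, amp) {
      s0 <- round(t0 * rate) + 1L
      if (s0 < 1L || s0 > n) return(x)
      s1 <- min(n, s0 + length(kern) - 1L)
      x[s0:s1] <- x[s0:s1] + amp * kern[seq_len(s1 - s0 + 1L)]
      x
    }
    calcium <- numeric(n)
    # pre-choice ramp: transient starting 4 s before choice, attenuated on
    # risky blocks
    ramp_kern_len <- round(4 * rate)
    ramp <- seq(0, 1, length.out = ramp_kern_len)
    for (i in seq_len(nrow(tr))) {
      att <- if (tr$block[i] >= 2L) params$prechoice_attenuation else 1
      s0 <- round((tr$t_choice[i] - 4) * rate) + 1L
      s1 <- s0 + ramp_kern_len - 1L
      if (s0 >= 1L && s1 <= n)
        calcium[s0:s1] <- calcium[s0:s1] +
          att * params$prechoice_amplitude * ramp
      if (tr$punished[i])
        calcium <- add_transient(calcium, tr$t_choice[i],
                                 params$punish_amplitude)
      calcium <- add_transient(calcium, tr$t_collect[i],
                               params$reward_amplitude)
    }
    control <- params$control_offset + artifact +
      stats::rnorm(n, 0, params$noise_sd)
    signal <- params$artifact_gain * artifact + calcium +
      stats::rnorm(n, 0, params$noise_sd)
    events <- rbind(
      data.frame(time = tr$t_choice, label = "choice", block = tr$block,
                 punished = tr$punished),
      data.frame(time = tr$t_collect, label = "collection",
                 block = tr$block, punished = tr$punished),
      data.frame(time = tr$t_choice[tr$punished], label = "punishment",
                 block = tr$block[tr$punished],
                 punished = rep(TRUE, sum(tr$punished))))
    events <- events[order(events$time), ]
    rownames(events) <- NULL
    photometry_recording(signal, control, rate, events)
  })
}
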