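#' Agent policy for simulated risky decision-making
#'
#' A softmax value-based agent that generates the behavioral pattern the
#' analyses target: fewer large-reward choices, slower latencies and more
#' aborts as punishment risk rises. Free-choice probability of the large
#' option is \code{plogis(inverse_temperature * (value_large -
#' risk_weight * p_punish - value_small))}; latencies are lognormal with mean
#' \code{latency_base_s + latency_risk_slope_s * p_punish}; aborts occur
#' before a choice with probability \code{abort_base_p}, raised to
#' \code{abort_post_punish_p} on the trial after a punishment, with targets
#' biased towards the large-reward screen.
#'
#' Default values put free-choice large-reward preference near 95/50/20
#' percent across the 0/50/75 percent risk blocks, the qualitative pattern of
#' a risk-averse mouse.
#'
#' @param value_large,value_small subjective reward utilities.
#' @param risk_weight utility penalty per unit punishment probability.
#' @param inverse_temperature softmax sharpness (>= 0).
#' @param latency_base_s,latency_risk_slope_s mean choice latency at zero risk
#'   and its increase per unit punishment probability (seconds).
#' @param init_latency_base_s,init_risk_slope_s mean post-ITI delay before
#'   the animal initiates the next trial, and its increase per unit
#'   punishment probability (seconds). Initiation delays are long-tailed
#'   (lognormal, sdlog 0.8): mice pause variably between trials, which also
#'   keeps event times irregular rather than metronomic.
#' @param abort_base_p,abort_post_punish_p abort probabilities.
#' @param omission_p probability a presented trial is omitted.
#' @return an object of class \code{agent_policy}.
#' @export
agent_policy <- function(value_large = 4, value_small = 1,
                         risk_weight = 6, inverse_temperature = 1,
                         latency_base_s = 2, latency_risk_slope_s = 3,
                         init_latency_base_s = 4, init_risk_slope_s = 4,
                         abort_base_p = 0.05, abort_post_punish_p = 0.5,
                         omission_p = 0) {
  p <- list(value_large = value_large, value_small = value_small,
            risk_weight = risk_weight,
            inverse_temperature = inverse_temperature,
            latency_base_s = latency_base_s,
            latency_risk_slope_s = latency_risk_slope_s,
            init_latency_base_s = init_latency_base_s,
            init_risk_slope_s = init_risk_slope_s,
            abort_base_p = abort_base_p,
            abort_post_punish_p = abort_post_punish_p,
            omission_p = omission_p)
  probs <- c(p$abort_base_p, p$abort_post_punish_p, p$omission_p)
  if (any(probs < 0 | probs > 1))
    stop("abort/omission probabilities must lie in [0, 1]", call. = FALSE)
  if (p$inverse_temperature < 0)
    stop("inverse_temperature must be >= 0", call. = FALSE)
  structure(p, class = "agent_policy")
}

#' Construct a behavioral session
#'
#' Bundles a schedule with the realized per-trial record and abort events.
#' Completed (non-omitted) trials must cover every schedule slot; omitted
#' presentations are carried alongside and do not count towards the block
#' trial totals.
#'
#' @param schedule a \code{session_schedule}.
#' @param trials data frame with one row per trial presentation: \code{slot},
#'   \code{block}, \code{kind}, \code{choice} (large/small/omission),
#'   \code{punished}, \code{t_init}, \code{t_choice}, \code{t_collect},
#'   \code{t_consume_end} (seconds from session start).
#' @param aborts data frame of abort events: \code{trial_index} (row of
#'   \code{trials}), \code{t_abort}, \code{target} (large/small).
#' @param pose optional pose track: data frame \code{frame}, \code{x},
#'   \code{y} at 30 frames/s.
#' @return an object of class \code{behavioral_session}.
#' @export
behavioral_session <- function(schedule, trials, aborts = NULL, pose = NULL) {
  if (is.null(aborts))
    aborts <- data.frame(trial_index = integer(0), t_abort = numeric(0),
                         target = character(0), stringsAsFactors = FALSE)
  comp <- trials[trials$choice != "omission", , drop = FALSE]
  ts <- cbind(comp$t_init, comp$t_choice, comp$t_collect, comp$t_consume_end)
  bad <- which(apply(ts, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1L && any(diff(r) <= 0)
  }))
  if (length(bad))
    stop("non-monotone timestamps in trial(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  structure(list(schedule = schedule, trials = trials, aborts = aborts,
                 pose = pose),
            class = "behavioral_session")
}

#' @export
print.behavioral_session <- function(x, ...) {
  comp <- completed_trials(x)
  cat("Behavioral session:", nrow(comp), "completed trials (",
      sum(x$trials$choice == "omission"), "omissions,",
      nrow(x$aborts), "aborts )\n")
  pct <- try(choice_percentages(x), silent = TRUE)
  if (!inherits(pct, "try-error")) {
    cat("  free-choice large %:",
        paste(round(pct$large_pct, 1), collapse = "/"), "\n")
  }
  invisible(x)
}

completed_trials <- function(session) {
  session$trials[session$trials$choice != "omission", , drop = FALSE]
}

#' Simulate a behavioral session from a schedule and policy
#'
#' Walks the schedule slot by slot, drawing choices, punishments, latencies,
#' aborts and omissions from the agent policy. Forced slots take the cued
#' side; forced large-reward slots deliver their scheduled shocks exactly;
#' free-choice large selections are punished i.i.d. at the block probability.
#' Omitted presentations are re-presented until the slot completes, as in the
#' task program.
#'
#' @param schedule a \code{session_schedule}.
#' @param policy an \code{\link{agent_policy}}.
#' @param seed integer seed; the session is deterministic given
#'   (schedule, policy, seed).
#' @return a \code{\link{behavioral_session}}.
#' @examples
#' sch <- build_rdt_schedule(task_config(), seed = 1)
#' ses <- simulate_behavior(sch, agent_policy(), seed = 1)
#' choice_percentages(ses)
#' @export
simulate_behavior <- function(schedule, policy = agent_policy(), seed = 1L) {
  stopifnot(inherits(schedule, "session_schedule"))
  cfg <- attr(schedule, "config")
  large_side <- attr(schedule, "large_side")
  with_seed(seed, {
    trials <- vector("list", 2L * nrow(schedule))
    aborts <- list()
    ti <- 0L
    t <- 5
    prev_punished <- FALSE
    for (i in seq_len(nrow(schedule))) {
      slot <- schedule[i, ]
      p_block <- if (slot$kind == "free") slot$punish_prob else
        cfg$block_punish_prob[slot$block]
      repeat {
        ti <- ti + 1L
        m_init <- policy$init_latency_base_s +
          policy$init_risk_slope_s * p_block
        t_init <- t + stats::rlnorm(1, log(m_init) - 0.32, 0.8)
        if (stats::runif(1) < policy$omission_p) {
          trials[[ti]] <- data.frame(
            slot = slot$slot, block = slot$block, kind = slot$kind,
            choice = "omission", punished = FALSE, t_init = t_init,
            t_choice = NA_real_, t_collect = NA_real_,
            t_consume_end = NA_real_, stringsAsFactors = FALSE)
          t <- t_init + cfg$omission_timeout_s + cfg$iti_s
          next
        }
        # abort events precede the eventual choice
        p_abort <- if (prev_punished) policy$abort_post_punish_p else
          policy$abort_base_p
        n_abort <- 0L
        t_ab <- numeric(0)
        tgt_ab <- character(0)
        tcur <- t_init
        while (n_abort < 3L && stats::runif(1) < p_abort) {
          n_abort <- n_abort + 1L
          tcur <- tcur + stats::rlnorm(1, log(1.2), 0.3)
          t_ab <- c(t_ab, tcur)
          tgt_ab <- c(tgt_ab,
                      if (stats::runif(1) < 0.75) "large" else "small")
        }
        m_lat <- policy$latency_base_s +
          policy$latency_risk_slope_s * p_block
        sdlog <- 0.4
        lat <- stats::rlnorm(1, log(m_lat) - sdlog^2 / 2, sdlog)
        t_choice <- tcur + lat
        choice <- switch(slot$kind,
          free = {
            u <- policy$value_large - policy$risk_weight * p_block -
              policy$value_small
            p_large <- stats::plogis(policy$inverse_temperature * u)
            if (stats::runif(1) < p_large) "large" else "small"
          },
          if (sub("forced_", "", slot$kind) == large_side) "large"
          else "small")
        punished <- if (choice != "large") FALSE
          else if (slot$kind == "free") stats::runif(1) < p_block
          else isTRUE(slot$scheduled_punish)
        t_collect <- t_choice + stats::rlnorm(1, log(1) - 0.045, 0.3)
        dur <- if (choice == "large") 2.5 else 1.5
        t_consume_end <- t_collect + stats::rlnorm(1, log(dur) - 0.02, 0.2)
        trials[[ti]] <- data.frame(
          slot = slot$slot, block = slot$block, kind = slot$kind,
          choice = choice, punished = punished, t_init = t_init,
          t_choice = t_choice, t_collect = t_collect,
          t_consume_end = t_consume_end, stringsAsFactors = FALSE)
        if (n_abort > 0L)
          aborts[[length(aborts) + 1L]] <- data.frame(
            trial_index = ti, t_abort = t_ab, target = tgt_ab,
            stringsAsFactors = FALSE)
        t <- t_consume_end + cfg$iti_s
        prev_punished <- punished
        break
      }
    }
    trials <- do.call(rbind, trials[seq_len(ti)])
    aborts <- if (length(aborts)) do.call(rbind, aborts) else NULL
    behavioral_session(schedule, trials, aborts)
  })
}
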