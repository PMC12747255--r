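# Shared fixtures, built in code at test time.

default_session <- function(seed = 11L, policy = agent_policy()) {
  sch <- build_rdt_schedule(task_config(), seed = seed)
  simulate_behavior(sch, policy, seed = seed + 1L)
}

# Minimal hand-built session: n trials, fixed timing, no simulator involved.
tiny_session <- function(choices = c("large", "small", "large"),
                         punished = c(FALSE, FALSE, TRUE),
                         blocks = c(1L, 1L, 1L),
                         kind = rep("free", length(choices)),
                         dt = 20) {
  n <- length(choices)
  t0 <- (seq_len(n) - 1L) * dt + 5
  trials <- data.frame(
    slot = seq_len(n), block = blocks, kind = kind, choice = choices,
    punished = punished, t_init = t0, t_choice = t0 + 2,
    t_collect = t0 + 3, t_consume_end = t0 + 5,
    stringsAsFactors = FALSE)
  cfg <- task_config(n_blocks = length(unique(blocks)),
                     trials_per_block = as.integer(n / length(unique(blocks))),
                     forced_per_block = 0L,
                     free_per_block = as.integer(n / length(unique(blocks))),
                     block_punish_prob = rep(0, length(unique(blocks))),
                     forced_shock_counts = rep(0L, length(unique(blocks))))
  sch <- data.frame(slot = seq_len(n), block = blocks, kind = kind,
                    scheduled_punish = FALSE, punish_prob = NA_real_,
                    stringsAsFactors = FALSE)
  attr(sch, "large_side") <- "left"
  attr(sch, "config") <- cfg
  class(sch) <- c("session_schedule", "data.frame")
  behavioral_session(sch, trials)
}

# Trace matrix with transients of known amplitude at known times.
impulse_traces <- function(n_neurons = 1L, n_samples = 2000L, rate = 20,
                           impulse_times = numeric(0), amplitude = 1) {
  v <- matrix(0, n_neurons, n_samples)
  for (tt in impulse_times) v[, round(tt * rate) + 1L] <- amplitude
  trace_matrix(v, rate)
}
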