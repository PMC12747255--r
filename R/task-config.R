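#' Task configuration for touchscreen reward-choice sessions
#'
#' Describes the block structure of the reward-magnitude (RM) and
#' risky-decision (RDT) tests: three 30-trial blocks, each opening with 8
#' forced-choice trials (4 per side) followed by 22 free-choice trials. In the
#' RDT, choosing the large-reward option can deliver a mild footshock with a
#' probability that rises across blocks (0, 50, 75 percent by default);
#' forced-choice large-reward trials carry exactly the block's shock
#' proportion (0, 2, 3 shocks out of 4).
#'
#' @param n_blocks number of trial blocks.
#' @param trials_per_block completed trials per block.
#' @param forced_per_block forced-choice trials opening each block.
#' @param free_per_block free-choice trials per block.
#' @param block_punish_prob per-block probability that a free-choice
#'   large-reward selection is punished.
#' @param forced_shock_counts per-block number of scheduled shocks on the 4
#'   forced large-reward trials.
#' @param large_volume_ul,small_volume_ul reward volumes (microlitres).
#' @param shock_mA footshock intensity (milliamperes).
#' @param iti_s inter-trial interval (seconds).
#' @param omission_timeout_s response window before a trial is scored as an
#'   omission (seconds).
#' @return an object of class \code{task_config}.
#' @examples
#' cfg <- task_config()
#' cfg$block_punish_prob
#' @export
task_config <- function(n_blocks = 3L,
                        trials_per_block = 30L,
                        forced_per_block = 8L,
                        free_per_block = 22L,
                        block_punish_prob = c(0, 0.5, 0.75),
                        forced_shock_counts = c(0L, 2L, 3L),
                        large_volume_ul = 20,
                        small_volume_ul = 5,
                        shock_mA = 0.1,
                        iti_s = 8,
                        omission_timeout_s = 30) {
  cfg <- structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    forced_per_block = as.integer(forced_per_block),
    free_per_block = as.integer(free_per_block),
    block_punish_prob = as.numeric(block_punish_prob),
    forced_shock_counts = as.integer(forced_shock_counts),
    large_volume_ul = large_volume_ul,
    small_volume_ul = small_volume_ul,
    shock_mA = shock_mA,
    iti_s = iti_s,
    omission_timeout_s = omission_timeout_s
  ), class = "task_config")
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  if (cfg$forced_per_block + cfg$free_per_block != cfg$trials_per_block)
    stop("invalid task config: forced_per_block + free_per_block must equal ",
         "trials_per_block", call. = FALSE)
  if (length(cfg$block_punish_prob) != cfg$n_blocks)
    stop("invalid task config: block_punish_prob must have one entry per block",
         call. = FALSE)
  if (length(cfg$forced_shock_counts) != cfg$n_blocks)
    stop("invalid task config: forced_shock_counts must have one entry per ",
         "block", call. = FALSE)
  if (any(cfg$block_punish_prob < 0 | cfg$block_punish_prob > 1))
    stop("invalid task config: block_punish_prob entries must lie in [0, 1]",
         call. = FALSE)
  n_forced_large <- cfg$forced_per_block %/% 2L
  if (any(cfg$forced_shock_counts < 0L |
          cfg$forced_shock_counts > n_forced_large))
    stop("invalid task config: forced_shock_counts must lie between 0 and ",
         "the number of forced large-reward trials per block (",
         n_forced_large, ")", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task config:", x$n_blocks, "blocks x", x$trials_per_block, "trials (",
      x$forced_per_block, "forced +", x$free_per_block, "free )\n")
  cat("  punish prob by block:", paste(x$block_punish_prob, collapse = "/"),
      "; forced shocks:", paste(x$forced_shock_counts, collapse = "/"), "\n")
  invisible(x)
}
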