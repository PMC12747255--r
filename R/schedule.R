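#' Build a risky-decision test (RDT) trial schedule
#'
#' Lays out every trial slot of a session: each block opens with the forced
#' trials (a balanced pseudorandom left/right sequence, 4 per side, with no
#' side repeated more than 3 times in a row) followed by the free-choice
#' trials. Scheduled punishment applies only to forced large-reward slots:
#' exactly \code{forced_shock_counts[b]} of the 4 forced large slots in block
#' \code{b} are marked punished, so forced trials deliver shocks at exactly
#' the block's probability. Free slots are punished at choice time with
#' probability \code{block_punish_prob[b]} (handled by the behavior
#' simulator or the real task program, not pre-scheduled).
#'
#' @param config a \code{\link{task_config}}.
#' @param seed integer seed controlling the pseudorandom forced-side order and
#'   which forced slots carry a scheduled shock.
#' @param large_side side ("left" or "right") assigned to the large reward for
#'   this subject.
#' @return a data frame of class \code{session_schedule} with one row per
#'   trial slot: \code{slot}, \code{block}, \code{kind} (forced_left,
#'   forced_right, free), \code{scheduled_punish}, \code{punish_prob},
#'   plus a \code{large_side} attribute.
#' @examples
#' sch <- build_rdt_schedule(task_config(), seed = 1)
#' table(sch$block, sch$kind)
#' @export
build_rdt_schedule <- function(config = task_config(), seed = 1L,
                               large_side = c("left", "right")) {
  validate_task_config(config)
  large_side <- match.arg(large_side)
  with_seed(seed, {
    rows <- lapply(seq_len(config$n_blocks), function(b) {
      sides <- forced_side_sequence(config$forced_per_block)
      kind <- c(paste0("forced_", sides),
                rep("free", config$free_per_block))
      large_slots <- which(sides == large_side)
      n_shock <- config$forced_shock_counts[b]
      shock_slots <- if (n_shock > 0L)
        sample(large_slots, n_shock) else integer(0)
      sp <- rep(FALSE, config$trials_per_block)
      sp[shock_slots] <- TRUE
      data.frame(
        block = b,
        kind = kind,
        scheduled_punish = sp,
        punish_prob = ifelse(kind == "free", config$block_punish_prob[b], NA),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out <- cbind(slot = seq_len(nrow(out)), out)
    attr(out, "large_side") <- large_side
    attr(out, "config") <- config
    class(out) <- c("session_schedule", "data.frame")
    out
  })
}

# Balanced left/right order with at most 3 consecutive repeats of a side.
forced_side_sequence <- function(n_forced) {
  n_half <- n_forced %/% 2L
  repeat {
    s <- sample(rep(c("left", "right"), n_half))
    if (max(rle(s)$lengths) <= 3L) return(s)
  }
}

#' Build a reward-magnitude (RM) discrimination schedule
#'
#' Identical block structure to the RDT but with all punishment probabilities
#' and forced shock counts set to zero: the no-risk training and comparison
#' session.
#'
#' @inheritParams build_rdt_schedule
#' @return a \code{session_schedule} (see \code{\link{build_rdt_schedule}}).
#' @export
build_rm_schedule <- function(config = task_config(), seed = 1L,
                              large_side = c("left", "right")) {
  validate_task_config(config)
  config$block_punish_prob <- rep(0, config$n_blocks)
  config$forced_shock_counts <- rep(0L, config$n_blocks)
  build_rdt_schedule(config, seed = seed, large_side = large_side)
}

#' Progressive-ratio press requirements
#'
#' Under the progressive-ratio schedule the touch requirement grows by 4 with
#' each earned reward: 4 presses for reward one, 8 for reward two, and so on.
#'
#' @param n_rewards number of rewards to generate requirements for.
#' @return integer vector of press counts, element i being the requirement
#'   for reward i.
#' @examples
#' build_pr_requirements(3)  # 4 8 12
#' @export
build_pr_requirements <- function(n_rewards) {
  if (!is.numeric(n_rewards) || length(n_rewards) != 1L || n_rewards < 1)
    stop("n_rewards must be a single count >= 1", call. = FALSE)
  4L * seq_len(as.integer(n_rewards))
}

#' Footshock sensitivity ladder
#'
#' The shock-sensitivity test delivers one shock every 10 seconds, ascending
#' in 0.02 mA increments to 0.50 mA, for 25 shocks in total. The nominal
#' 0.00 mA start is treated as the pre-test baseline and not emitted as a
#' shock, which reconciles the stated range with the stated count.
#'
#' @return data frame with columns \code{intensity_mA} and \code{t_s}
#'   (delivery time, seconds from the first shock).
#' @examples
#' ladder <- build_shock_ladder()
#' nrow(ladder); max(ladder$intensity_mA)
#' @export
build_shock_ladder <- function() {
  intensity <- seq(0.02, 0.50, by = 0.02)
  data.frame(intensity_mA = intensity,
             t_s = 10 * (seq_along(intensity) - 1L))
}

#' @export
print.session_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Session schedule:", nrow(x), "slots,",
      length(unique(x$block)), "blocks; large side:",
      attr(x, "large_side"), "\n")
  shocks <- tapply(x$scheduled_punish, x$block, sum)
  cat("  scheduled forced shocks per block:",
      paste(shocks, collapse = "/"), "\n")
  invisible(x)
}
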