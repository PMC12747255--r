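# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a sub-seed from a master seed and an operation tag
#'
#' Stable across sessions: hashes the tag's UTF-8 bytes into [0, 2^31).
#' @param seed master seed (integer).
#' @param tag character scalar naming the operation.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147480009
  as.integer((as.numeric(seed) + h) %% 2147480009)
}

#' Circularly shift a vector
#' @noRd
circ_shift <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

#' Circular moving mean over all window start positions
#'
#' For a vector of length n, returns an n-vector m where m[s] is the mean of
#' the length-L window starting at position s, wrapping around the end.
#' Equivalent to epoch means of every circular shift of the series.
#' @noRd
circ_window_means <- function(x, L) {
  n <- length(x)
  stopifnot(L >= 1L, L <= n)
  cs <- cumsum(c(x, x[seq_len(L - 1L)]))
  starts <- seq_len(n)
  ends <- starts + L - 1L
  (cs[ends] - c(0, cs[starts[-1L] - 1L])) / L
}

#' Enforce a minimum consecutive-run length on a logical mask
#'
#' TRUE runs shorter than `min_run` bins are set FALSE; NA treated as FALSE.
#' @param mask logical vector.
#' @param min_run minimum run length (bins).
#' @return logical vector of the same length.
#' @export
apply_min_run <- function(mask, min_run) {
  mask <- !is.na(mask) & mask
  if (min_run <= 1L || !any(mask)) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

#' Construct a significance mask object
#'
#' A logical per-bin mask carrying its alpha level, minimum-run constraint and
#' resample count; every TRUE run is guaranteed to be at least `min_run` long.
#' @param significant logical vector (pre min-run filtering).
#' @param alpha alpha level used.
#' @param min_run minimum consecutive significant bins.
#' @param n_resamples number of permutations/bootstraps behind the mask.
#' @param time_s optional per-bin times (seconds).
#' @return an object of class \code{significance_mask}.
#' @export
significance_mask <- function(significant, alpha, min_run, n_resamples,
                              time_s = NULL) {
  m <- apply_min_run(significant, min_run)
  structure(list(significant = m, alpha = alpha, min_run = min_run,
                 n_resamples = n_resamples, time_s = time_s),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  r <- rle(x$significant)
  n_runs <- sum(r$values)
  cat("Significance mask:", length(x$significant), "bins,",
      sum(x$significant), "significant in", n_runs, "run(s)\n")
  cat("  alpha =", x$alpha, ", min_run =", x$min_run,
      ", resamples =", x$n_resamples, "\n")
  invisible(x)
}

# trapezoidal integral on a uniform or non-uniform grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2 * diff(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
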