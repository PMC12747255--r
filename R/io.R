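#' Write / read a behavioral session as CSV tables
#'
#' The trial table has one row per trial presentation with columns
#' \code{trial_index}, \code{slot}, \code{block}, \code{kind}, \code{choice},
#' \code{punished}, \code{t_init}, \code{t_choice}, \code{t_collect},
#' \code{t_consume_end}; abort events go to a companion CSV
#' (\code{trial_index}, \code{t_abort}, \code{target}).
#'
#' @param session a \code{\link{behavioral_session}}.
#' @param path trial-table CSV path.
#' @param abort_path companion abort CSV path (default: \code{path} with
#'   \code{_aborts} suffix).
#' @return \code{path}, invisibly.
#' @export
write_trial_table <- function(session, path,
                              abort_path = sub("\\.csv$", "_aborts.csv",
                                               path)) {
  tr <- session$trials
  tr <- cbind(trial_index = seq_len(nrow(tr)), tr)
  utils::write.csv(tr, path, row.names = FALSE)
  utils::write.csv(session$aborts, abort_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param schedule optional \code{session_schedule}; reconstructed minimally
#'   from the table when absent.
#' @export
read_trial_table <- function(path,
                             abort_path = sub("\\.csv$", "_aborts.csv",
                                              path),
                             schedule = NULL) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("block", "kind", "choice", "punished", "t_init", "t_choice",
                "t_collect", "t_consume_end")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  aborts <- if (file.exists(abort_path))
    utils::read.csv(abort_path, stringsAsFactors = FALSE) else NULL
  if (is.null(schedule)) {
    comp <- tr[tr$choice != "omission", , drop = FALSE]
    schedule <- data.frame(slot = seq_len(nrow(comp)), block = comp$block,
                           kind = comp$kind,
                           scheduled_punish = FALSE,
                           punish_prob = NA_real_,
                           stringsAsFactors = FALSE)
    attr(schedule, "large_side") <- "left"
    attr(schedule, "config") <- task_config(
      n_blocks = length(unique(comp$block)),
      trials_per_block = as.integer(nrow(comp) /
                                      length(unique(comp$block))),
      forced_per_block = as.integer(sum(comp$kind != "free" &
                                          comp$block == comp$block[1L])),
      free_per_block = as.integer(sum(comp$kind == "free" &
                                        comp$block == comp$block[1L])),
      block_punish_prob = rep(0, length(unique(comp$block))),
      forced_shock_counts = rep(0L, length(unique(comp$block))))
    class(schedule) <- c("session_schedule", "data.frame")
  }
  behavioral_session(schedule, tr[, setdiff(names(tr), "trial_index")],
                     aborts)
}

#' Export an ensemble assignment (and optional dynamics) as CSV
#'
#' @param assignment an \code{ensemble_assignment}.
#' @param path output CSV path.
#' @param exclusive optional per-neuron exclusive labels.
#' @param dynamics optional \code{ensemble_dynamics} for the same neurons.
#' @return \code{path}, invisibly.
#' @export
write_ensemble_csv <- function(assignment, path, exclusive = NULL,
                               dynamics = NULL) {
  df <- as.data.frame(assignment)
  df$category <- attr(assignment, "category")
  if (!is.null(exclusive)) df$exclusive_label <- exclusive
  if (!is.null(dynamics)) df$status <- dynamics$per_neuron$status
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every knob of a simulate-and-analyze run. All stochastic stages
#' derive their seeds from \code{master_seed} plus a stable operation tag,
#' so a configuration reruns identically.
#'
#' @param task a \code{\link{task_config}}.
#' @param policy an \code{\link{agent_policy}}.
#' @param neurons a \code{\link{neuron_spec}}.
#' @param photometry a \code{\link{photometry_params}}.
#' @param window peri-event extraction window (s).
#' @param n_shuffle,k_sd ensemble identification parameters.
#' @param n_folds decoding folds.
#' @param master_seed master seed.
#' @param out_dir output directory.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(task = task_config(), policy = agent_policy(),
                       neurons = neuron_spec(),
                       photometry = photometry_params(),
                       window = c(-10, 10), n_shuffle = 1000L, k_sd = 1.5,
                       n_folds = 5L, master_seed = 1L,
                       out_dir = tempfile("riskensembles_run")) {
  structure(list(task = task, policy = policy, neurons = neurons,
                 photometry = photometry, window = window,
                 n_shuffle = n_shuffle, k_sd = k_sd, n_folds = n_folds,
                 master_seed = master_seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the simulate-align-identify-analyze pipeline
#'
#' Simulates an RDT session (behavior, traces, photometry) under the
#' configuration, aligns traces to choice events, identifies the pre-choice
#' ensemble separately for the safe block and the trial-matched pooled risky
#' blocks, classifies Conserved/Lost/New dynamics, runs the decoding
#' control and the photometry pre-choice contrast, and writes CSV outputs
#' plus a JSON manifest to \code{config$out_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with the session, assignments, dynamics, decoding and
#'   photometry results, and the manifest path.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- config$master_seed
  sch <- build_rdt_schedule(config$task, seed = derive_seed(ms, "schedule"))
  ses <- simulate_behavior(sch, config$policy,
                           seed = derive_seed(ms, "behavior"))
  sim <- simulate_traces(ses, config$neurons,
                         seed = derive_seed(ms, "traces"))
  tr <- completed_trials(ses)
  epoch <- standard_epoch("pre_choice")
  safe_t <- tr$t_choice[tr$block == 1L & tr$kind == "free"]
  risky_t <- tr$t_choice[tr$block >= 2L & tr$kind == "free"]
  risky_t <- match_trial_counts(safe_t, risky_t,
                                seed = derive_seed(ms, "match"))
  tens_safe <- zscore_per_trial(extract_peri_event(sim$traces, safe_t,
                                                   config$window))
  tens_risky <- zscore_per_trial(extract_peri_event(sim$traces, risky_t,
                                                    config$window))
  a_safe <- identify_ensemble(tens_safe, epoch,
                              n_shuffle = config$n_shuffle,
                              k_sd = config$k_sd,
                              seed = derive_seed(ms, "ident_safe"))
  a_risky <- identify_ensemble(tens_risky, epoch,
                               n_shuffle = config$n_shuffle,
                               k_sd = config$k_sd,
                               seed = derive_seed(ms, "ident_risky"))
  dyn <- classify_dynamics(a_safe, a_risky)
  dec <- decode_ensemble(sim$traces, safe_t, epoch,
                         seed = derive_seed(ms, "decode"),
                         n_folds = config$n_folds)
  rec <- simulate_photometry(ses, config$photometry,
                             seed = derive_seed(ms, "photometry"))
  dff <- fit_control_and_dff(rec)
  write_trial_table(ses, file.path(config$out_dir, "trials.csv"))
  write_ensemble_csv(a_safe, file.path(config$out_dir,
                                       "ensemble_safe.csv"),
                     dynamics = dyn)
  utils::write.csv(sim$truth, file.path(config$out_dir,
                                        "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "riskensembles",
    version = as.character(utils::packageVersion("riskensembles")),
    master_seed = ms,
    n_neurons = config$neurons$n_neurons,
    n_shuffle = config$n_shuffle, k_sd = config$k_sd,
    dynamics_fractions = as.list(dyn$fractions),
    decoding_mean_f1 = dec$mean_f1,
    decoding_baseline_f1 = dec$baseline_mean_f1)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  list(session = ses, truth = sim$truth, safe = a_safe, risky = a_risky,
       dynamics = dyn, decoding = dec, dff = dff,
       manifest = manifest_path)
}
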