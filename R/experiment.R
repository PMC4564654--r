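#' Multi-run experiment configuration
#'
#' @param training a [training_config()]. Its `seed` field is overridden
#'   per run with `base_seed + run`.
#' @param corpus_spec a [corpus_spec()].
#' @param n_runs number of independently initialised runs (default 10).
#' @param base_seed integer; run `i` uses seed `base_seed + i` for weight
#'   initialisation and presentation shuffling.
#' @param exclusion_threshold minimum final training agreement (as a
#'   fraction) for a run to be retained (default 0.10). A run is excluded
#'   when its final agreement falls below
#'   `max(2 * 1/24, exclusion_threshold)`, i.e. below twice chance level —
#'   the operational signature of a run trapped in a shallow local minimum
#'   right after initialisation.
#' @param shared_corpus if `TRUE` (default) all runs train on the same
#'   corpus realisation; if `FALSE` each run regenerates the corpus with
#'   seed `corpus_spec$seed + run`.
#' @param include_baseline keep the untrained epoch-0 checkpoint in
#'   trajectory records (default `FALSE`, matching a test schedule that
#'   starts after the first checkpoint interval).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(training, corpus_spec, n_runs = 10L,
                              base_seed = 1L, exclusion_threshold = 0.10,
                              shared_corpus = TRUE,
                              include_baseline = FALSE) {
  stopifnot(inherits(training, "training_config"),
            inherits(corpus_spec, "corpus_spec"),
            n_runs >= 1L,
            exclusion_threshold >= 0, exclusion_threshold <= 1)
  structure(
    list(training = training, corpus_spec = corpus_spec,
         n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
         exclusion_threshold = exclusion_threshold,
         shared_corpus = isTRUE(shared_corpus),
         include_baseline = isTRUE(include_baseline)),
    class = "experiment_config")
}

#' A scaled-down replication experiment
#'
#' The canonical study conditions shrunk to a desk scale while preserving
#' their structure: 60 base melodies in the original 315:41 major:minor
#' ratio (53 major, 7 minor), closed under transposition to 720 training
#' items per epoch; 2,000 training epochs with a checkpoint every 200,
#' giving the same 10 test times with the third checkpoint at 30% of
#' training; 8 runs.
#'
#' Two parameters deliberately differ from the general-purpose defaults
#' (see the package vignette for the full rationale). The learning rate is
#' 8e-5: a 720-item corpus drawn from 60 base patterns is far less diverse
#' than the full diet, so at faster rates the network reaches its asymptote
#' before the first checkpoint and the recorded trajectory is flat; the
#' reduced rate keeps the learning timeline proportional to the full-scale
#' design, with condition curves still rising at the 30% checkpoint and
#' training agreement ending below ceiling. And each run trains on its own
#' corpus realisation (`shared_corpus = FALSE`): a 60-melody synthetic draw
#' carries substantial sampling noise that a full-sized real corpus does
#' not, and averaging runs over independent realisations integrates that
#' noise out instead of letting one lucky or unlucky draw set every run's
#' learning speed.
#'
#' @param seed integer master seed; corpus generation uses `seed` and run
#'   `i` uses `seed + i`.
#' @param n_epochs total epochs (default 2000); the checkpoint interval is
#'   kept at a tenth of this.
#' @param n_runs number of runs (default 8).
#' @return An [experiment_config()].
#' @export
reduced_experiment_config <- function(seed = 1L, n_epochs = 2000L,
                                      n_runs = 8L) {
  stopifnot(n_epochs %% 10L == 0L)
  experiment_config(
    training = training_config(n_epochs = n_epochs,
                               checkpoint_interval = n_epochs %/% 10L,
                               learning_rate = 8e-5),
    corpus_spec = corpus_spec(n_major = 53L, n_minor = 7L, seed = seed),
    n_runs = n_runs,
    base_seed = seed,
    shared_corpus = FALSE)
}

#' Run a multi-seed training experiment
#'
#' Trains `n_runs` independently initialised networks on the (shared or
#' per-run) transposition-augmented corpus, evaluates every checkpoint on
#' the three test conditions and on the training corpus, and excludes runs
#' whose final training agreement shows no learning progress (see
#' [experiment_config()]). Trajectories are returned for retained runs
#' only; exclusions are logged with the criterion value.
#'
#' @param cfg an [experiment_config()].
#' @param testsets test battery (default [build_test_sets()]).
#' @param progress print a line per run (default `FALSE`).
#' @return An object of class `tonal_experiment`: list with `trajectories`
#'   (records over retained runs), `agreement` (per retained run and
#'   checkpoint), `retained_runs`, `excluded_runs`, `final_agreement`
#'   (all runs), and `config`.
#' @export
run_experiment <- function(cfg, testsets = build_test_sets(),
                           progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  chance <- 100 / 24
  cutoff <- max(2 * chance, 100 * cfg$exclusion_threshold)

  shared <- NULL
  if (cfg$shared_corpus) {
    shared <- augment_by_transposition(generate_corpus(cfg$corpus_spec))
  }

  traj <- list(); agree <- list()
  final_agreement <- numeric(cfg$n_runs)
  retained <- integer(0); excluded <- integer(0)

  for (run in seq_len(cfg$n_runs)) {
    corp <- shared
    if (is.null(corp)) {
      sp <- cfg$corpus_spec
      sp$seed <- sp$seed + run
      corp <- augment_by_transposition(generate_corpus(sp))
    }
    run_seed <- cfg$base_seed + run
    tcfg <- cfg$training
    tcfg$seed <- run_seed
    net <- init_network(seed = run_seed)
    fit <- train_network(net, corp, tcfg)
    ev <- evaluate_trajectory(fit, testsets, corpus = corp, run_id = run,
                              include_baseline = cfg$include_baseline)
    fa <- ev$agreement$agreement[which.max(ev$agreement$epoch)]
    final_agreement[run] <- fa
    if (fa < cutoff) {
      excluded <- c(excluded, run)
      message(sprintf(
        "run %d excluded: final training agreement %.1f%% below cutoff %.1f%%",
        run, fa, cutoff))
    } else {
      retained <- c(retained, run)
      traj[[length(traj) + 1L]] <- ev$records
      agree[[length(agree) + 1L]] <- ev$agreement
    }
    if (progress) {
      message(sprintf("run %d/%d: final agreement %.1f%%",
                      run, cfg$n_runs, fa))
    }
  }
  if (length(retained) == 0L) {
    stop("experiment failed: every run fell below the exclusion cutoff",
         call. = FALSE)
  }
  structure(
    list(trajectories = do.call(rbind, traj),
         agreement = do.call(rbind, agree),
         retained_runs = retained, excluded_runs = excluded,
         final_agreement = final_agreement, config = cfg),
    class = "tonal_experiment")
}

#' @export
print.tonal_experiment <- function(x, ...) {
  cat(sprintf(
    "<tonal_experiment> %d runs (%d retained, %d excluded), %d checkpoints\n",
    x$config$n_runs, length(x$retained_runs), length(x$excluded_runs),
    length(unique(x$trajectories$epoch))))
  cat(sprintf(" final training agreement (retained): %s%%\n",
              paste(sprintf("%.0f", x$final_agreement[x$retained_runs]),
                    collapse = ", ")))
  invisible(x)
}

#' Condition-by-epoch trajectory means
#'
#' Means of a trajectory measure over retained runs, one row per
#' condition x epoch cell.
#'
#' @param x a `tonal_experiment` or a trajectory records data.frame.
#' @param dv `"percent_correct"` or `"activation"`.
#' @return data.frame with `epoch`, `condition`, `mean`, `sd`, `n_runs`.
#' @export
condition_means <- function(x, dv = c("percent_correct", "activation")) {
  dv <- match.arg(dv)
  records <- if (inherits(x, "tonal_experiment")) x$trajectories else x
  agg <- aggregate(records[[dv]],
                   by = list(epoch = records$epoch,
                             condition = records$condition),
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- data.frame(epoch = agg$epoch, condition = agg$condition,
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n_runs = agg$x[, "n"])
  out[order(out$epoch, out$condition), ]
}
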