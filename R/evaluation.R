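#' Test conditions probing scale and harmony sensitivity
#'
#' @return Character vector of the three condition names, in canonical
#'   order: `in_scale_regular`, `in_scale_irregular`,
#'   `out_of_scale_irregular`.
#' @export
test_conditions <- function() {
  c("in_scale_regular", "in_scale_irregular", "out_of_scale_irregular")
}

# Nine-tone fixture sequences, one row of rationale each:
# - regular: three 3-tone groups arpeggiating C-major triads in I-V-I or
#   I-IV-I order, so a regular harmonic progression is implied;
# - irregular (in-scale): only C-major scale tones, ordered so that no three
#   consecutive tones outline any major or minor triad;
# - out-of-scale: chromatic sequences drawing on {C#, D#, F#, G#, A#}, also
#   avoiding consecutive triad outlines.
# All share length 9 so condition comparisons are not confounded by length.
test_fixture_chromas <- function() {
  list(
    in_scale_regular = list(
      reg_1 = c(0, 4, 7, 7, 11, 2, 0, 4, 7),   # I - V  - I
      reg_2 = c(0, 4, 7, 5, 9, 0, 0, 4, 7),    # I - IV - I
      reg_3 = c(0, 7, 4, 2, 7, 11, 0, 4, 7),   # I - V  - I
      reg_4 = c(0, 4, 7, 0, 5, 9, 7, 4, 0),    # I - IV - I
      reg_5 = c(4, 0, 7, 11, 7, 2, 7, 4, 0)    # I - V  - I
    ),
    in_scale_irregular = list(
      irr_1 = c(0, 2, 4, 5, 7, 9, 11, 9, 7),
      irr_2 = c(0, 5, 4, 2, 11, 9, 2, 4, 5),
      irr_3 = c(2, 7, 5, 9, 11, 4, 9, 2, 0),
      irr_4 = c(5, 4, 2, 9, 7, 4, 2, 0, 5),
      irr_5 = c(11, 9, 5, 4, 2, 7, 9, 4, 2)
    ),
    out_of_scale_irregular = list(
      oos_1 = c(1, 8, 3, 10, 8, 1, 3, 8, 1),
      oos_2 = c(6, 1, 8, 3, 1, 10, 8, 3, 6),
      oos_3 = c(3, 0, 6, 2, 8, 4, 10, 1, 3),
      oos_4 = c(10, 5, 8, 3, 10, 1, 8, 11, 10),
      oos_5 = c(6, 8, 10, 1, 8, 3, 2, 8, 6)
    )
  )
}

#' Build the three test sets
#'
#' Deterministic nine-tone fixtures, five per condition, probing the two
#' tonal sensitivities separately. Sequences in the in-scale conditions use
#' C-major scale tones only; the regular-harmony sequences additionally
#' arpeggiate C-major triads in I-V-I or I-IV-I order while the irregular
#' sequences avoid any consecutive triad outline; the out-of-scale
#' sequences contain chromatic (non-C-major) tones. Listeners enculturated
#' to Western music would hear all of them relative to C major, so C major
#' is the correct key for every sequence.
#'
#' @return Named list of three `test_set` objects, each with fields
#'   `condition`, `sequences` (5 melodies) and `correct_key` (C major).
#' @export
build_test_sets <- function() {
  fix <- test_fixture_chromas()
  c_major <- key_label(0L, "major")
  sets <- lapply(test_conditions(), function(cond) {
    seqs <- lapply(names(fix[[cond]]), function(id) {
      melody(fix[[cond]][[id]], c_major, id = id)
    })
    structure(list(condition = cond, sequences = seqs, correct_key = c_major),
              class = "test_set")
  })
  names(sets) <- test_conditions()
  sets
}

#' @export
print.test_set <- function(x, ...) {
  cat(sprintf("<test_set> %s: %d sequences, correct key index %d\n",
              x$condition, length(x$sequences), x$correct_key$index))
  invisible(x)
}

#' Read the identified key off the network
#'
#' The identified key is the output unit with the largest raw activation.
#' An exact tie is broken towards the lowest key index, with a warning.
#'
#' @param s a `network_state`.
#' @param m a `melody`.
#' @return A [key_label()].
#' @export
identify_key <- function(s, m) {
  o <- forward(s, m)
  top <- which(o == max(o))
  if (length(top) > 1L) {
    warning(sprintf(
      "tie between output units %s; choosing the lowest key index",
      paste(top - 1L, collapse = ", ")), call. = FALSE)
  }
  decode_key(top[1L] - 1L)
}

#' Percent of test sequences identified as the correct key
#'
#' @param s a `network_state`.
#' @param t a `test_set`.
#' @return Percentage in 0..100 (multiples of 20 for a 5-sequence set).
#' @export
percent_correct <- function(s, t) {
  stopifnot(inherits(t, "test_set"))
  hits <- vapply(t$sequences, function(m) {
    identify_key(s, m)$index == t$correct_key$index
  }, logical(1))
  100 * mean(hits)
}

#' Mean normalized correct-key activation
#'
#' The raw activation of the correct-key output unit lies in (-1, 1); it is
#' mapped linearly to \[0, 1\] via `(o + 1) / 2` and averaged over the test
#' set's sequences.
#'
#' @param s a `network_state`.
#' @param t a `test_set`.
#' @return Mean normalized activation in \[0, 1\].
#' @export
normalized_correct_key_activation <- function(s, t) {
  stopifnot(inherits(t, "test_set"))
  acts <- vapply(t$sequences, function(m) {
    (forward(s, m)[t$correct_key$index + 1L] + 1) / 2
  }, numeric(1))
  mean(acts)
}

#' Agreement rate between identified and labelled keys
#'
#' Fraction of corpus melodies for which the network's argmax key equals
#' the key label (the teacher signal), reported as a percentage.
#'
#' @param s a `network_state`.
#' @param c a non-empty `melody_corpus`.
#' @return Percentage in 0..100.
#' @export
agreement_rate <- function(s, c) {
  stopifnot(inherits(s, "network_state"), inherits(c, "melody_corpus"))
  if (length(c$melodies) == 0L) stop("corpus is empty", call. = FALSE)
  idx_list <- lapply(c$melodies, function(m) as.integer(state_indices(s, m)))
  out <- cpp_outputs(s$W1, s$b1, s$W2, s$b2, s$W3, s$b3, idx_list)
  pred <- max.col(out, ties.method = "first") - 1L
  truth <- vapply(c$melodies, function(m) m$key$index, integer(1))
  100 * mean(pred == truth)
}

#' Evaluate a training trajectory
#'
#' Read-only evaluation of every checkpoint against the three test sets
#' (percent correct and normalized correct-key activation per condition)
#' and, if a corpus is supplied, the training agreement rate. Records are
#' sorted by epoch and condition.
#'
#' @param checkpoints a `training_run` or its list of checkpoints.
#' @param testsets the list from [build_test_sets()].
#' @param corpus optional `melody_corpus` for the agreement curve.
#' @param run_id identifier stored on every record (default 1).
#' @param include_baseline keep the untrained epoch-0 checkpoint in the
#'   records (default `TRUE`).
#' @return A list of class `trajectory_evaluation` with `records` (a
#'   data.frame: `run_id`, `epoch`, `condition`, `percent_correct`,
#'   `activation`) and `agreement` (data.frame `run_id`, `epoch`,
#'   `agreement`, or `NULL`).
#' @export
evaluate_trajectory <- function(checkpoints, testsets, corpus = NULL,
                                run_id = 1L, include_baseline = TRUE) {
  if (inherits(checkpoints, "training_run")) {
    checkpoints <- checkpoints$checkpoints
  }
  if (length(checkpoints) == 0L) stop("no checkpoints to evaluate",
                                      call. = FALSE)
  if (!include_baseline) {
    checkpoints <- Filter(function(cp) cp$epoch > 0L, checkpoints)
  }
  conds <- test_conditions()
  stopifnot(all(conds %in% names(testsets)))

  rows <- lapply(checkpoints, function(cp) {
    per_cond <- lapply(conds, function(cond) {
      ts <- testsets[[cond]]
      data.frame(run_id = run_id, epoch = cp$epoch, condition = cond,
                 percent_correct = percent_correct(cp$state, ts),
                 activation = normalized_correct_key_activation(cp$state, ts),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_cond)
  })
  records <- do.call(rbind, rows)
  records$condition <- factor(records$condition, levels = conds)
  records <- records[order(records$epoch, records$condition), ]
  rownames(records) <- NULL

  agreement <- NULL
  if (!is.null(corpus)) {
    agreement <- data.frame(
      run_id = run_id,
      epoch = vapply(checkpoints, `[[`, integer(1), "epoch"),
      agreement = vapply(checkpoints,
                         function(cp) agreement_rate(cp$state, corpus),
                         numeric(1)))
    agreement <- agreement[order(agreement$epoch), ]
    rownames(agreement) <- NULL
  }
  structure(list(records = records, agreement = agreement),
            class = "trajectory_evaluation")
}
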