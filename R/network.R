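#' Initialise the key-identification network
#'
#' The network is a fully connected multilayer perceptron with a 2,232-unit
#' positional chroma input layer (186 positions x 12 chromas), two hidden
#' layers of 45 and 30 units, and a 24-unit key output layer. All hidden
#' and output units use the hyperbolic-tangent sigmoid. Parameters are
#' drawn i.i.d. from the uniform distribution on
#' `[-init_scale, init_scale]`.
#'
#' `layer_sizes` may be overridden to build a miniature of the same
#' architecture (used, e.g., for gradient checking); the canonical model is
#' the default `c(2232, 45, 30, 24)`.
#'
#' @param seed optional integer seed for reproducible initialisation.
#' @param init_scale half-width of the uniform initialiser (default 0.1).
#' @param layer_sizes integer 4-vector: input, hidden 1, hidden 2, output.
#' @return An object of class `network_state` with weight matrices
#'   `W1` (input x hidden1), `W2` (hidden1 x hidden2), `W3`
#'   (hidden2 x output), bias vectors `b1`, `b2`, `b3`, the `layer_sizes`,
#'   the `seed`, and the training `epoch` (0 for a fresh network).
#' @export
init_network <- function(seed = NULL, init_scale = 0.1,
                         layer_sizes = c(2232L, 45L, 30L, 24L)) {
  stopifnot(init_scale > 0, length(layer_sizes) == 4L, all(layer_sizes >= 1L))
  layer_sizes <- as.integer(layer_sizes)
  with_local_seed(seed, {
    u <- function(nr, nc) {
      matrix(runif(nr * nc, -init_scale, init_scale), nr, nc)
    }
    structure(
      list(W1 = u(layer_sizes[1], layer_sizes[2]),
           b1 = runif(layer_sizes[2], -init_scale, init_scale),
           W2 = u(layer_sizes[2], layer_sizes[3]),
           b2 = runif(layer_sizes[3], -init_scale, init_scale),
           W3 = u(layer_sizes[3], layer_sizes[4]),
           b3 = runif(layer_sizes[4], -init_scale, init_scale),
           layer_sizes = layer_sizes, seed = seed, epoch = 0L),
      class = "network_state")
  })
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> layers %s, epoch %d\n",
              paste(x$layer_sizes, collapse = "-"), x$epoch))
  invisible(x)
}

#' Hyperbolic-tangent sigmoid activation
#'
#' `f(x) = (exp(x) - exp(-x)) / (exp(x) + exp(-x))`, with range (-1, 1).
#' Evaluated through the numerically stable [base::tanh()] so that large
#' `|x|` saturates to +/-1 instead of overflowing; the two forms agree to
#' machine precision wherever the literal form is finite.
#'
#' @param x numeric vector.
#' @return `tanh(x)`.
#' @export
activation <- function(x) tanh(x)

#' Binarize output activations
#'
#' Readout rule mapping a raw output in (-1, 1) to 1 when strictly
#' positive and 0 otherwise (an exact 0 maps to 0). Used only for
#' interpreting outputs as identified/not-identified; it plays no role in
#' the training gradient.
#'
#' @param outputs numeric vector with entries in (-1, 1).
#' @return Integer vector of 0s and 1s.
#' @export
binarize <- function(outputs) {
  if (any(!is.finite(outputs)) || any(outputs <= -1) || any(outputs >= 1)) {
    stop("outputs must lie strictly inside (-1, 1)", call. = FALSE)
  }
  as.integer(outputs > 0)
}

# active-input indices for a melody, validated against the state's capacity
state_indices <- function(s, m) {
  if (s$layer_sizes[1] %% 12L != 0L) {
    stop("input layer size must be a multiple of 12", call. = FALSE)
  }
  max_len <- s$layer_sizes[1] %/% 12L
  if (length(m$chromas) > max_len) {
    stop(sprintf("melody has %d tones but the network accepts up to %d",
                 length(m$chromas), max_len), call. = FALSE)
  }
  melody_input_indices(m)
}

#' Forward pass
#'
#' Propagates one melody (or a raw encoded input vector) through the three
#' affine-plus-tanh layers and returns the 24 raw output activations, each
#' in (-1, 1).
#'
#' @param s a `network_state`.
#' @param x a `melody`, or a numeric vector of length `layer_sizes[1]`.
#' @return Numeric vector of output activations (length `layer_sizes[4]`).
#' @export
forward <- function(s, x) {
  stopifnot(inherits(s, "network_state"))
  idx <- if (inherits(x, "melody")) {
    state_indices(s, x)
  } else {
    if (!is.numeric(x) || length(x) != s$layer_sizes[1]) {
      stop(sprintf("input must be a melody or a numeric vector of length %d",
                   s$layer_sizes[1]), call. = FALSE)
    }
    which(x != 0)
  }
  if (is.numeric(x) && !inherits(x, "melody") && !all(x %in% c(0, 1))) {
    # general dense input: fall back to plain matrix arithmetic
    a1 <- tanh(drop(crossprod(s$W1, x)) + s$b1)
    a2 <- tanh(drop(crossprod(s$W2, a1)) + s$b2)
    return(tanh(drop(crossprod(s$W3, a2)) + s$b3))
  }
  drop(cpp_forward(s$W1, s$b1, s$W2, s$b2, s$W3, s$b3,
                   as.integer(idx))$a3)
}

#' Backpropagation gradients for one item
#'
#' Gradients of the squared-error loss `0.5 * sum((output - target)^2)`
#' (raw tanh outputs, not binarized) with respect to every weight and bias.
#' Exposed mainly so the analytic gradients can be verified against
#' finite-difference approximations.
#'
#' @param s a `network_state`.
#' @param m a `melody`.
#' @param target numeric target vector of length `layer_sizes[4]`, or a
#'   [key_label()] (converted with the \{0, 1\} teacher coding).
#' @return List with `gW1`, `gb1`, `gW2`, `gb2`, `gW3`, `gb3`, and the
#'   item `loss`.
#' @export
network_gradients <- function(s, m, target) {
  stopifnot(inherits(s, "network_state"), inherits(m, "melody"))
  if (inherits(target, "key_label")) {
    t24 <- numeric(s$layer_sizes[4])
    t24[target$index + 1L] <- 1
    target <- t24
  }
  stopifnot(length(target) == s$layer_sizes[4])
  cpp_gradients(s$W1, s$b1, s$W2, s$b2, s$W3, s$b3,
                as.integer(state_indices(s, m)), target)
}

#' Training configuration
#'
#' @param n_epochs total number of training epochs (one epoch = one
#'   presentation of every corpus item).
#' @param learning_rate positive step size for online gradient descent
#'   (default 0.01).
#' @param checkpoint_interval epochs between snapshots (default 5000). A
#'   final checkpoint is forced if the interval does not divide `n_epochs`.
#' @param shuffle reshuffle the presentation order every epoch (default
#'   `TRUE`).
#' @param seed integer seed controlling shuffling (default 1).
#' @param bipolar_targets use \{-0.9, +0.9\} teacher coding instead of the
#'   default \{0, 1\} coding (default `FALSE`). With the default coding the
#'   "absent" target 0 sits at the midpoint of the tanh output range.
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_epochs, learning_rate = 0.01,
                            checkpoint_interval = 5000L, shuffle = TRUE,
                            seed = 1L, bipolar_targets = FALSE) {
  stopifnot(n_epochs >= 1, learning_rate > 0, checkpoint_interval >= 1)
  structure(
    list(n_epochs = as.integer(n_epochs), learning_rate = learning_rate,
         checkpoint_interval = as.integer(checkpoint_interval),
         shuffle = isTRUE(shuffle), seed = as.integer(seed),
         target_low = if (bipolar_targets) -0.9 else 0,
         target_high = if (bipolar_targets) 0.9 else 1),
    class = "training_config")
}

#' Checkpoint schedule of a training run
#'
#' Epochs at which the network state is snapshotted: every
#' `checkpoint_interval` epochs, with the final epoch forced if the
#' interval does not divide `n_epochs`. The untrained epoch-0 baseline is
#' stored in addition to these.
#'
#' @param n_epochs,checkpoint_interval see [training_config()].
#' @return Increasing integer vector of checkpoint epochs (excluding 0).
#' @examples
#' checkpoint_epochs(50000, 5000)  # the canonical 10 test times
#' @export
checkpoint_epochs <- function(n_epochs, checkpoint_interval) {
  eps <- if (checkpoint_interval > n_epochs) integer(0) else {
    seq.int(checkpoint_interval, n_epochs, by = checkpoint_interval)
  }
  if (length(eps) == 0L || eps[length(eps)] != n_epochs) {
    eps <- c(eps, n_epochs)
  }
  as.integer(eps)
}

#' Train the network on a melody corpus
#'
#' Online (per-item) stochastic gradient descent on the squared error
#' between the raw tanh outputs and the one-hot teacher signal. Every
#' corpus item is presented exactly once per epoch, in an order reshuffled
#' each epoch from the run seed. The network state is snapshotted at the
#' [checkpoint_epochs()] schedule plus the untrained epoch-0 baseline; no
#' parameter ever changes during an evaluation.
#'
#' @param s a fresh `network_state` with the canonical layer sizes.
#' @param c a `melody_corpus`; ordinarily transposition-augmented (see
#'   [augment_by_transposition()]) so that no key is privileged.
#' @param cfg a [training_config()].
#' @return An object of class `training_run`: list with `checkpoints`
#'   (each a list of `epoch`, `state`, `training_loss`), the per-epoch
#'   mean loss `epoch_loss`, and `config`.
#' @export
train_network <- function(s, c, cfg) {
  stopifnot(inherits(s, "network_state"), inherits(c, "melody_corpus"),
            inherits(cfg, "training_config"))
  if (length(c$melodies) == 0L) stop("cannot train on an empty corpus",
                                     call. = FALSE)
  idx_list <- lapply(c$melodies, function(m) as.integer(state_indices(s, m)))
  key_idx <- vapply(c$melodies, function(m) m$key$index + 1L, integer(1))
  cps <- checkpoint_epochs(cfg$n_epochs, cfg$checkpoint_interval)

  res <- with_local_seed(cfg$seed, {
    cpp_train(s$W1, s$b1, s$W2, s$b2, s$W3, s$b3,
              idx_list, key_idx,
              cfg$learning_rate, cfg$n_epochs, cps,
              cfg$target_low, cfg$target_high, cfg$shuffle)
  })

  wrap <- function(cp) {
    st <- s
    st$W1 <- cp$W1; st$b1 <- drop(cp$b1)
    st$W2 <- cp$W2; st$b2 <- drop(cp$b2)
    st$W3 <- cp$W3; st$b3 <- drop(cp$b3)
    st$epoch <- cp$epoch
    list(epoch = cp$epoch, state = st, training_loss = cp$training_loss)
  }
  checkpoints <- c(list(list(epoch = 0L, state = s, training_loss = NA_real_)),
                   lapply(res$checkpoints, wrap))
  structure(list(checkpoints = checkpoints,
                 epoch_loss = as.numeric(res$epoch_loss),
                 config = cfg),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  eps <- vapply(x$checkpoints, `[[`, integer(1), "epoch")
  cat(sprintf("<training_run> %d epochs, %d checkpoints (epochs %s%s)\n",
              x$config$n_epochs, length(eps),
              paste(head(eps, 6L), collapse = ", "),
              if (length(eps) > 6L) ", ..." else ""))
  invisible(x)
}
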