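# shared fixture builders for the test suite

c_major_set <- c(0, 2, 4, 5, 7, 9, 11)

# tiny corpus: a handful of short base melodies, optionally augmented
tiny_corpus <- function(n_major = 2, n_minor = 1, seed = 11, augment = FALSE) {
  sp <- corpus_spec(n_major = n_major, n_minor = n_minor,
                    length_min = 17, length_max = 25, seed = seed)
  co <- generate_corpus(sp)
  if (augment) augment_by_transposition(co) else co
}

# a miniature of the network architecture: 2 serial positions x 12 chromas
# input (24 units), small hidden layers
mini_network <- function(seed = 3, sizes = c(24, 8, 6, 4)) {
  init_network(seed = seed, layer_sizes = sizes)
}

# deterministic state whose outputs are known: zero weights, chosen output bias
contrived_state <- function(b3) {
  s <- init_network(seed = 1)
  s$W1[] <- 0; s$W2[] <- 0; s$W3[] <- 0
  s$b1[] <- 0; s$b2[] <- 0
  s$b3 <- b3
  s
}

# balanced synthetic trajectory records: n_subj runs x 3 conditions x epochs,
# cell means given by `effects` (condition x epoch matrix), iid noise on top
synthetic_records <- function(n_subj, epochs, effects = NULL, sd_noise = 1,
                              sd_subject = 1) {
  conds <- test_conditions()
  if (is.null(effects)) {
    effects <- matrix(0, length(conds), length(epochs))
  }
  grid <- expand.grid(run_id = seq_len(n_subj),
                      condition = conds, epoch = epochs,
                      stringsAsFactors = FALSE)
  subj_eff <- rnorm(n_subj, sd = sd_subject)
  grid$percent_correct <- mapply(function(r, cond, ep) {
    effects[match(cond, conds), match(ep, epochs)] +
      subj_eff[r] + rnorm(1, sd = sd_noise)
  }, grid$run_id, grid$condition, grid$epoch)
  grid$activation <- grid$percent_correct / 100
  grid
}
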