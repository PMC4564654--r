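test_that("the tanh activation matches its closed form and is odd", {
  expect_identical(activation(0), 0)
  expect_equal(activation(1), (exp(1) - exp(-1)) / (exp(1) + exp(-1)))
  xs <- seq(-5, 5, by = 0.37)
  expect_equal(activation(-xs), -activation(xs))
  expect_true(all(abs(activation(c(-1e4, 1e4))) == 1))  # saturates, no overflow
})

test_that("binarization thresholds strictly at zero and validates its domain", {
  expect_identical(binarize(c(0.3, -0.2, 0)), c(1L, 0L, 0L))
  expect_error(binarize(c(0.5, 1)), "inside")
  expect_error(binarize(-1), "inside")
})

test_that("initialisation is seed-reproducible and bounded by init_scale", {
  a <- init_network(seed = 5, init_scale = 0.1)
  b <- init_network(seed = 5, init_scale = 0.1)
  expect_identical(a, b)
  c <- init_network(seed = 6, init_scale = 0.1)
  expect_false(identical(a$W1, c$W1))
  for (p in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expect_true(all(abs(a[[p]]) <= 0.1))
  }
  expect_identical(dim(a$W1), c(2232L, 45L))
  expect_identical(dim(a$W2), c(45L, 30L))
  expect_identical(dim(a$W3), c(30L, 24L))
  expect_identical(a$epoch, 0L)
})

test_that("the forward pass stays in (-1, 1) and zero parameters give zero", {
  s <- contrived_state(b3 = rep(0, 24))
  m <- generate_melody(key_label(0, "major"), 17, seed = 1)
  expect_identical(forward(s, m), rep(0, 24))

  net <- init_network(seed = 9)
  o <- forward(net, m)
  expect_length(o, 24)
  expect_true(all(o > -1 & o < 1))
  # melody path and dense encoded path agree
  expect_equal(forward(net, encode_melody(m)), o, tolerance = 1e-14)
})

test_that("backprop gradients match central finite differences on a miniature", {
  set.seed(42)
  for (rep in 1:3) {
    s <- mini_network(seed = rep, sizes = c(24, 8, 6, 4))
    m <- melody(sample(0:11, 2, replace = TRUE), key_label(0, "major"))
    target <- runif(4, -0.5, 0.5)
    g <- network_gradients(s, m, target)

    loss_at <- function(st) {
      o <- forward(st, m)
      0.5 * sum((o - target)^2)
    }
    h <- 1e-6
    for (p in c("W1", "W2", "W3", "b1", "b2", "b3")) {
      gp <- g[[paste0("g", p)]]
      # probe a subset of entries to keep the check fast; compare as a
      # vector so near-zero single entries cannot dominate
      idx <- sample(length(s[[p]]), min(25, length(s[[p]])))
      num <- vapply(idx, function(i) {
        sp <- s; sp[[p]][i] <- sp[[p]][i] + h
        sm <- s; sm[[p]][i] <- sm[[p]][i] - h
        (loss_at(sp) - loss_at(sm)) / (2 * h)
      }, numeric(1))
      rel <- sqrt(sum((num - gp[idx])^2)) /
        max(sqrt(sum(num^2)), sqrt(sum(gp[idx]^2)), 1e-10)
      expect_lt(rel, 1e-5)
    }
  }
})

test_that("gradients for inactive input rows are exactly zero", {
  s <- mini_network(seed = 1)
  m <- melody(c(3, 7), key_label(0, "major"))
  g <- network_gradients(s, m, runif(4))
  active <- c(3 + 1, 12 + 7 + 1)
  expect_true(all(g$gW1[-active, ] == 0))
  expect_true(any(g$gW1[active, ] != 0))
})

test_that("checkpoint schedules include a forced final epoch", {
  expect_identical(checkpoint_epochs(50000, 5000), as.integer(seq(5000, 50000, 5000)))
  expect_identical(checkpoint_epochs(11, 5), c(5L, 10L, 11L))
  expect_identical(checkpoint_epochs(3, 5), 3L)
})

test_that("training is seed-deterministic and loss decreases on a toy problem", {
  corp <- tiny_corpus(n_major = 2, n_minor = 0, seed = 3, augment = TRUE)
  net <- init_network(seed = 4)
  cfg <- training_config(n_epochs = 60, checkpoint_interval = 20, seed = 4,
                         learning_rate = 0.05)
  run1 <- train_network(net, corp, cfg)
  run2 <- train_network(net, corp, cfg)
  expect_identical(run1$checkpoints[[4]]$state$W1,
                   run2$checkpoints[[4]]$state$W1)

  # epoch-0 baseline plus three scheduled checkpoints, strictly increasing
  eps <- vapply(run1$checkpoints, `[[`, integer(1), "epoch")
  expect_identical(eps, c(0L, 20L, 40L, 60L))
  expect_identical(run1$checkpoints[[1]]$state$W1, net$W1)

  # moving-window mean loss is non-increasing on this separable problem
  loss <- run1$epoch_loss
  w <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
  w <- w[!is.na(w)]
  expect_true(all(diff(w) <= 1e-8))

  # separable toy corpus is mastered quickly
  final <- run1$checkpoints[[4]]$state
  expect_identical(agreement_rate(final, corp), 100)
})

test_that("a trained network generalises transposition above chance", {
  corp <- tiny_corpus(n_major = 3, n_minor = 0, seed = 8, augment = TRUE)
  net <- init_network(seed = 8)
  cfg <- training_config(n_epochs = 150, checkpoint_interval = 150, seed = 8,
                         learning_rate = 0.05)
  run <- train_network(net, corp, cfg)
  final <- run$checkpoints[[length(run$checkpoints)]]$state
  # hold-out style probe: transposed copies of the base melodies carry the
  # transposed key; far above the 1/24 chance rate
  expect_gt(agreement_rate(final, corp), 50)
})

test_that("training rejects degenerate inputs", {
  empty <- structure(list(melodies = list(), spec = NULL, augmented = TRUE),
                     class = "melody_corpus")
  net <- init_network(seed = 1)
  cfg <- training_config(n_epochs = 5, checkpoint_interval = 5)
  expect_error(train_network(net, empty, cfg), "empty")
  # a wildly excessive learning rate drives the loss to divergence or
  # saturation without crashing R; divergence is reported with the epoch
  corp <- tiny_corpus(n_major = 1, n_minor = 0, seed = 2, augment = TRUE)
  big <- training_config(n_epochs = 5, checkpoint_interval = 5,
                         learning_rate = 1e6)
  res <- tryCatch(train_network(net, corp, big), error = function(e) e)
  if (inherits(res, "error")) expect_match(conditionMessage(res), "epoch")
})
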