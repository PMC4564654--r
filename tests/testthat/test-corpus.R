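test_that("key labels round-trip through their index and cover all 24 keys", {
  indices <- integer(0)
  for (mode in c("major", "minor")) {
    for (tonic in 0:11) {
      k <- key_label(tonic, mode)
      expect_identical(decode_key(k$index)$tonic, tonic)
      expect_identical(decode_key(k$index)$mode, mode)
      indices <- c(indices, k$index)
    }
  }
  expect_setequal(indices, 0:23)
  expect_error(decode_key(24), "0\\.\\.23")
  expect_error(key_label(12, "major"), "0\\.\\.11")
})

test_that("default profiles are valid sampling distributions", {
  for (mode in c("major", "minor")) {
    p <- default_profile(mode)
    expect_length(p, 12)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    out_deg <- setdiff(0:11, scale_degrees(mode))
    expect_lte(sum(p[out_deg + 1]), 0.05)
  }
})

test_that("generated melodies start and end on the tonic and are mostly in-scale", {
  m <- generate_melody(key_label(0, "major"), 17, seed = 1)
  expect_length(m$chromas, 17)
  expect_identical(m$chromas[1], 0L)
  expect_identical(m$chromas[17], 0L)
  expect_gte(mean(m$chromas %in% c_major_set), 0.95)

  m2 <- generate_melody(key_label(9, "minor"), 186, seed = 2)
  expect_length(m2$chromas, 186)
  expect_identical(m2$chromas[1], 9L)
  expect_identical(m2$chromas[186], 9L)

  expect_error(generate_melody(key_label(0, "major"), 5, seed = 1), "17\\.\\.186")
  expect_error(generate_melody(key_label(0, "major"), 17, profile = rep(1, 12)),
               "sum to 1")
})

test_that("out-of-scale content is capped at the configured rate", {
  # stress profile with maximal allowed chromatic weight
  p <- default_profile("major", out_of_scale_mass = 0.05)
  for (seed in 1:20) {
    m <- generate_melody(key_label(5, "major"), 30, profile = p,
                         out_of_scale_rate = 0.05, seed = seed)
    in_scale <- (scale_degrees("major") + 5) %% 12
    expect_lte(mean(!(m$chromas %in% in_scale)), 0.05)
  }
})

test_that("corpus generation honours counts, length range and the seed", {
  sp <- corpus_spec(n_major = 5, n_minor = 3, length_min = 17,
                    length_max = 40, seed = 7)
  co <- generate_corpus(sp)
  modes <- vapply(co$melodies, function(m) m$key$mode, character(1))
  lens <- vapply(co$melodies, function(m) length(m$chromas), integer(1))
  expect_length(co$melodies, 8)
  expect_identical(sum(modes == "major"), 5L)
  expect_identical(sum(modes == "minor"), 3L)
  expect_true(all(lens >= 17 & lens <= 40))
  expect_false(co$augmented)

  co2 <- generate_corpus(sp)
  expect_identical(co, co2)  # bit-reproducible given the seed

  expect_error(generate_corpus(corpus_spec(n_major = 0, n_minor = 0)),
               "zero melodies")
})

test_that("transposition shifts chromas and tonic modulo 12", {
  m <- melody(c(0, 4, 7), key_label(0, "major"))
  t2 <- transpose_melody(m, 2)
  expect_identical(t2$chromas, c(2L, 6L, 9L))
  expect_identical(t2$key$tonic, 2L)
  expect_identical(t2$key$mode, "major")
  expect_identical(transpose_melody(m, 0)$chromas, m$chromas)
  expect_identical(transpose_melody(m, 12), transpose_melody(m, 0))
  expect_identical(transpose_melody(m, -1)$chromas,
                   transpose_melody(m, 11)$chromas)
})

test_that("transposition augmentation yields 12 same-mode copies per melody", {
  co <- tiny_corpus(n_major = 2, n_minor = 3)
  ca <- augment_by_transposition(co)
  expect_length(ca$melodies, 60)
  expect_true(ca$augmented)
  expect_error(augment_by_transposition(ca), "already")

  # every same-mode key present exactly once per base melody
  base <- vapply(ca$melodies, function(m) sub("_T\\d+$", "", m$id), character(1))
  for (b in unique(base)) {
    group <- ca$melodies[base == b]
    keys <- vapply(group, function(m) m$key$index, integer(1))
    expect_length(unique(keys), 12)
    expect_length(unique(vapply(group, function(m) m$key$mode, character(1))), 1)
  }

  # length multiset conserved x12
  l0 <- sort(vapply(co$melodies, function(m) length(m$chromas), integer(1)))
  l1 <- sort(vapply(ca$melodies, function(m) length(m$chromas), integer(1)))
  expect_identical(l1, rep(l0, each = 12))
})

test_that("chroma distributions are tonic-relative and key-invariant", {
  one <- structure(list(melodies = list(melody(c(0, 0, 0), key_label(0, "major"))),
                        spec = NULL, augmented = FALSE),
                   class = "melody_corpus")
  expect_equal(chroma_distribution(one, "major"), c(1, rep(0, 11)))
  expect_error(chroma_distribution(one, "minor"), "no minor")

  ca <- tiny_corpus(n_major = 3, n_minor = 1, augment = TRUE)
  pooled <- chroma_distribution(ca, "major")
  expect_equal(sum(pooled), 1, tolerance = 1e-12)
  # after augmentation each key's own distribution equals the pooled one
  for (tonic in c(0, 4, 10)) {
    sub <- Filter(function(m) m$key$mode == "major" && m$key$tonic == tonic,
                  ca$melodies)
    subc <- structure(list(melodies = sub, spec = NULL, augmented = TRUE),
                      class = "melody_corpus")
    expect_equal(chroma_distribution(subc, "major"), pooled, tolerance = 1e-12)
  }
  # out-of-scale degrees carry no more mass than the configured cap
  out_deg <- setdiff(0:11, scale_degrees("major"))
  expect_lte(sum(pooled[out_deg + 1]), ca$spec$out_of_scale_rate)
})

test_that("profile correlation matches expectations and rejects constants", {
  v <- default_profile("major")
  expect_equal(profile_correlation(v, v), 1)
  expect_equal(profile_correlation(v, -v + 2), -1)
  expect_error(profile_correlation(rep(1 / 12, 12), v), "constant")
  expect_error(profile_correlation(v[1:6], v), "length 12")
})

test_that("corpora round-trip through JSON Lines", {
  co <- tiny_corpus(n_major = 2, n_minor = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(co, path)
  back <- read_corpus_jsonl(path)
  expect_length(back$melodies, length(co$melodies))
  for (i in seq_along(co$melodies)) {
    expect_identical(back$melodies[[i]]$chromas, co$melodies[[i]]$chromas)
    expect_identical(back$melodies[[i]]$key$index, co$melodies[[i]]$key$index)
    expect_identical(back$melodies[[i]]$id, co$melodies[[i]]$id)
  }
})
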