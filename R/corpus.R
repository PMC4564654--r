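#' Default scale-degree sampling profiles
#'
#' Tonic-relative sampling weights over the 12 chromatic degrees used by the
#' melody generator. The in-scale weights follow the shape of the classic
#' probe-tone tonal hierarchy for the mode (tonic heaviest, then dominant
#' and mediant), renormalised so that 98% of the mass is in-scale; the
#' remaining 2% is spread evenly over out-of-scale degrees, emulating the
#' occasional chromatic ornament found in real songbook melodies. For the
#' minor mode the natural-minor set carries the in-scale mass and the raised
#' seventh (degree 11) receives a reduced but non-negligible share.
#'
#' @param mode `"major"` or `"minor"`.
#' @param out_of_scale_mass total weight given to out-of-scale degrees
#'   (default 0.02).
#' @return Numeric 12-vector of non-negative weights summing to 1;
#'   position `i` is degree `i - 1` above the tonic.
#' @export
default_profile <- function(mode = c("major", "minor"), out_of_scale_mass = 0.02) {
  mode <- match.arg(mode)
  stopifnot(out_of_scale_mass >= 0, out_of_scale_mass < 1)
  w <- numeric(12L)
  if (mode == "major") {
    in_deg <- scale_degrees("major")
    # tonal-hierarchy-shaped weights: tonic, supertonic, mediant,
    # subdominant, dominant, submediant, leading tone
    w[in_deg + 1L] <- c(6.35, 3.48, 4.38, 4.09, 5.19, 3.66, 2.88)
  } else {
    in_deg <- scale_degrees("minor", raised_seventh = TRUE)
    w[c(0L, 2L, 3L, 5L, 7L, 8L, 10L) + 1L] <-
      c(6.33, 3.52, 5.38, 3.53, 4.75, 3.98, 3.34)
    w[12L] <- 1.9  # raised leading tone, common but not dominant
  }
  out_deg <- setdiff(0:11, in_deg)
  w[in_deg + 1L] <- w[in_deg + 1L] / sum(w[in_deg + 1L]) * (1 - out_of_scale_mass)
  w[out_deg + 1L] <- out_of_scale_mass / length(out_deg)
  w
}

validate_profile <- function(profile, out_of_scale_rate, mode, arg = "profile") {
  if (!is.numeric(profile) || length(profile) != 12L) {
    stop(sprintf("`%s` must be a numeric vector of 12 degree weights", arg),
         call. = FALSE)
  }
  if (any(profile < 0)) {
    stop(sprintf("`%s` must be non-negative", arg), call. = FALSE)
  }
  if (abs(sum(profile) - 1) > 1e-9) {
    stop(sprintf("`%s` must sum to 1 (tolerance 1e-9)", arg), call. = FALSE)
  }
  out_deg <- setdiff(0:11, scale_degrees(mode))
  if (sum(profile[out_deg + 1L]) > out_of_scale_rate + 1e-12) {
    stop(sprintf(
      "`%s` places %.3f weight on out-of-scale degrees, above the cap %.3f",
      arg, sum(profile[out_deg + 1L]), out_of_scale_rate), call. = FALSE)
  }
  invisible(profile)
}

#' Specification of a synthetic melody corpus
#'
#' Captures the study conditions under which a training corpus is generated:
#' how many major- and minor-key base melodies, their length range in tones,
#' the tonic-relative scale-degree sampling profile per mode, the cap on
#' out-of-scale tone content per melody, and the seed. The defaults
#' reproduce a children's-songbook-like corpus: 315 major and 41 minor
#' melodies of 17 to 186 tones, overwhelmingly in-scale.
#'
#' @param n_major number of major-key base melodies (default 315).
#' @param n_minor number of minor-key base melodies (default 41).
#' @param length_min,length_max tone-count range (defaults 17 and 186).
#' @param profile_major,profile_minor 12-vectors of degree weights (see
#'   [default_profile()]).
#' @param out_of_scale_rate maximum proportion of out-of-scale tones allowed
#'   in a melody (default 0.05).
#' @param seed integer seed making generation reproducible.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_major = 315L, n_minor = 41L,
                        length_min = 17L, length_max = 186L,
                        profile_major = default_profile("major"),
                        profile_minor = default_profile("minor"),
                        out_of_scale_rate = 0.05,
                        seed = 1L) {
  stopifnot(n_major >= 0, n_minor >= 0,
            length_min >= 17L, length_max <= 186L, length_min <= length_max,
            out_of_scale_rate >= 0, out_of_scale_rate <= 1,
            length(seed) == 1L, is.finite(seed))
  validate_profile(profile_major, out_of_scale_rate, "major", "profile_major")
  validate_profile(profile_minor, out_of_scale_rate, "minor", "profile_minor")
  structure(
    list(n_major = as.integer(n_major), n_minor = as.integer(n_minor),
         length_min = as.integer(length_min), length_max = as.integer(length_max),
         profile_major = profile_major, profile_minor = profile_minor,
         out_of_scale_rate = out_of_scale_rate, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

new_melody <- function(id, chromas, key) {
  structure(list(id = id, chromas = as.integer(chromas), key = key),
            class = "melody")
}

#' Construct a melody by hand
#'
#' @param chromas integer vector of tone chromas in 0..11, in temporal order.
#' @param key a [key_label()] (the key listeners would perceive).
#' @param id identifier string.
#' @return An object of class `melody` with fields `id`, `chromas`, `key`.
#' @export
melody <- function(chromas, key, id = "melody") {
  if (length(chromas) < 1L) stop("a melody needs at least one tone", call. = FALSE)
  if (length(chromas) > 186L) {
    stop("melodies longer than 186 tones are not supported", call. = FALSE)
  }
  if (any(is.na(chromas)) || any(chromas != as.integer(chromas)) ||
      any(chromas < 0L) || any(chromas > 11L)) {
    stop("`chromas` must be integers in 0..11", call. = FALSE)
  }
  stopifnot(inherits(key, "key_label"))
  new_melody(id, chromas, key)
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("<melody '%s'> %d tones in key index %d (%s)\n",
              x$id, length(x$chromas), x$key$index, x$key$mode))
  cat(" chromas:", paste(head(x$chromas, 20L), collapse = " "),
      if (length(x$chromas) > 20L) "..." else "", "\n")
  invisible(x)
}

#' Generate one key-labelled melody
#'
#' Samples a tone-chroma sequence from a tonic-relative scale-degree profile
#' rotated to the requested key. The melody begins and ends on the tonic so
#' that a single stable key is clearly established, and the proportion of
#' out-of-scale tones is capped at `out_of_scale_rate` (tones in excess of
#' the cap are resampled from the in-scale part of the profile).
#'
#' @param key a [key_label()].
#' @param length number of tones, between 17 and 186.
#' @param profile 12-vector of tonic-relative degree weights.
#' @param out_of_scale_rate maximum proportion of out-of-scale tones.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [generate_corpus()]).
#' @return A `melody`.
#' @examples
#' m <- generate_melody(key_label(0, "major"), 17, seed = 1)
#' mean(m$chromas %in% c(0, 2, 4, 5, 7, 9, 11))  # in-scale proportion
#' @export
generate_melody <- function(key, length,
                            profile = default_profile(key$mode),
                            out_of_scale_rate = 0.05,
                            seed = NULL) {
  stopifnot(inherits(key, "key_label"))
  if (length(length) != 1L || is.na(length) || length < 17L || length > 186L) {
    stop("melody `length` must be a single integer in 17..186", call. = FALSE)
  }
  length <- as.integer(length)
  validate_profile(profile, out_of_scale_rate, key$mode)

  in_deg <- scale_degrees(key$mode)
  in_chroma <- (in_deg + key$tonic) %% 12L
  # rotate the tonic-relative profile to absolute chromas
  prob <- numeric(12L)
  prob[((0:11 + key$tonic) %% 12L) + 1L] <- profile
  if (sum(prob[in_chroma + 1L]) <= 0) {
    stop("profile has no in-scale mass; cannot generate a tonal melody",
         call. = FALSE)
  }

  with_local_seed(seed, {
    body <- if (length > 2L) {
      sample(0:11, length - 2L, replace = TRUE, prob = prob)
    } else integer(0)
    chromas <- c(key$tonic, body, key$tonic)
    # cap the out-of-scale content; resample the excess from in-scale mass
    oos <- which(!(chromas %in% in_chroma))
    max_oos <- floor(out_of_scale_rate * length)
    if (length(oos) > max_oos) {
      fix <- oos[seq.int(max_oos + 1L, length(oos))]
      prob_in <- prob
      prob_in[setdiff(0:11, in_chroma) + 1L] <- 0
      chromas[fix] <- sample(0:11, length(fix), replace = TRUE,
                             prob = prob_in / sum(prob_in))
    }
    new_melody(sprintf("%s%d_gen", substr(key$mode, 1, 3), key$index),
               chromas, key)
  })
}

#' Generate a key-labelled melody corpus
#'
#' Generates `n_major` major-key and `n_minor` minor-key base melodies
#' according to a [corpus_spec()]. Lengths are sampled uniformly on
#' `[length_min, length_max]`. Base melodies are generated in C major and
#' A minor; transposition augmentation ([augment_by_transposition()])
#' makes the base-key choice immaterial.
#'
#' @param spec a [corpus_spec()].
#' @return An object of class `melody_corpus`: a list with `melodies`,
#'   `spec`, and the logical flag `augmented`.
#' @examples
#' corp <- generate_corpus(corpus_spec(n_major = 3, n_minor = 1, seed = 7))
#' length(corp$melodies)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_major + spec$n_minor
  if (n == 0L) stop("corpus spec requests zero melodies", call. = FALSE)
  with_local_seed(spec$seed, {
    lengths <- sample(seq.int(spec$length_min, spec$length_max), n,
                      replace = TRUE)
    melodies <- vector("list", n)
    maj_key <- key_label(0L, "major")   # C major
    min_key <- key_label(9L, "minor")   # A minor
    for (i in seq_len(n)) {
      major <- i <= spec$n_major
      m <- generate_melody(
        if (major) maj_key else min_key,
        lengths[i],
        profile = if (major) spec$profile_major else spec$profile_minor,
        out_of_scale_rate = spec$out_of_scale_rate
      )
      m$id <- sprintf("%s_%03d", if (major) "maj" else "min",
                      if (major) i else i - spec$n_major)
      melodies[[i]] <- m
    }
    structure(list(melodies = melodies, spec = spec, augmented = FALSE),
              class = "melody_corpus")
  })
}

#' @export
print.melody_corpus <- function(x, ...) {
  modes <- vapply(x$melodies, function(m) m$key$mode, character(1))
  cat(sprintf("<melody_corpus> %d melodies (%d major, %d minor)%s\n",
              length(x$melodies), sum(modes == "major"), sum(modes == "minor"),
              if (isTRUE(x$augmented)) ", transposition-augmented" else ""))
  invisible(x)
}

#' Transpose a melody
#'
#' Shifts every chroma by `semitones` modulo 12 and moves the key tonic
#' identically; the mode, length, and temporal order are unchanged.
#'
#' @param m a `melody`.
#' @param semitones integer shift (reduced modulo 12).
#' @return The transposed `melody`.
#' @examples
#' m <- melody(c(0, 4, 7), key_label(0, "major"))
#' transpose_melody(m, 2)$chromas  # 2 6 9, now D major
#' @export
transpose_melody <- function(m, semitones) {
  stopifnot(inherits(m, "melody"), length(semitones) == 1L, is.finite(semitones))
  s <- as.integer(semitones) %% 12L
  new_melody(m$id, (m$chromas + s) %% 12L,
             key_label((m$key$tonic + s) %% 12L, m$key$mode))
}

#' Close a corpus under same-mode transposition
#'
#' Replaces every base melody by its 12 transpositions, one per key of the
#' same mode, so that all keys within a mode share an identical
#' tonic-relative tone distribution and the learner can have no key-specific
#' bias. With the default 315 + 41 base melodies the result presents
#' 4,272 training items per epoch.
#'
#' @param c a non-augmented `melody_corpus`.
#' @return The augmented `melody_corpus` (12 times as many melodies).
#' @export
augment_by_transposition <- function(c) {
  stopifnot(inherits(c, "melody_corpus"))
  if (isTRUE(c$augmented)) {
    stop("corpus is already transposition-augmented", call. = FALSE)
  }
  out <- vector("list", 12L * length(c$melodies))
  k <- 0L
  for (m in c$melodies) {
    for (s in 0:11) {
      k <- k + 1L
      t <- transpose_melody(m, s)
      t$id <- sprintf("%s_T%02d", m$id, s)
      out[[k]] <- t
    }
  }
  structure(list(melodies = out, spec = c$spec, augmented = TRUE),
            class = "melody_corpus")
}

#' Pooled tonic-relative chroma distribution of a corpus
#'
#' Rotates each melody's chromas so the tonic is degree 0, pools counts over
#' all melodies of the requested mode, and normalises to relative
#' frequencies.
#'
#' @param c a `melody_corpus`.
#' @param mode `"major"` or `"minor"`.
#' @return Numeric 12-vector summing to 1; position `i` is degree `i - 1`.
#' @export
chroma_distribution <- function(c, mode = c("major", "minor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(c, "melody_corpus"))
  sel <- Filter(function(m) m$key$mode == mode, c$melodies)
  if (length(sel) == 0L) {
    stop(sprintf("corpus contains no %s-mode melodies", mode), call. = FALSE)
  }
  counts <- numeric(12L)
  for (m in sel) {
    deg <- (m$chromas - m$key$tonic) %% 12L
    counts <- counts + tabulate(deg + 1L, nbins = 12L)
  }
  counts / sum(counts)
}

#' Pearson correlation between two degree profiles
#'
#' Validation hook for comparing a generated corpus's tone distribution with
#' a published reference profile.
#'
#' @param d,reference numeric 12-vectors; neither may be constant.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
profile_correlation <- function(d, reference) {
  if (length(d) != 12L || length(reference) != 12L) {
    stop("both profiles must have length 12", call. = FALSE)
  }
  if (sd(d) == 0 || sd(reference) == 0) {
    stop("correlation is undefined for a constant profile", call. = FALSE)
  }
  cor(d, reference)
}
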