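#' Positional pitch-class encoding
#'
#' A melody is presented to the network as a fixed-width binary vector of
#' 186 serial-position blocks of 12 chroma units each (2,232 inputs in
#' total). Position block `p` holds a single 1 at the chroma sounding at
#' serial position `p`; blocks beyond the melody's length are all zero, so
#' absent positions contribute nothing to the first affine layer. Coding the
#' serial position explicitly lets the network distinguish melodies that use
#' the same tones in different temporal orders.
#'
#' @param m a `melody` of 1 to 186 tones.
#' @param max_length capacity of the encoder in tones (default 186).
#' @return Numeric binary vector of length `12 * max_length`.
#' @examples
#' v <- encode_melody(melody(c(0, 4, 7), key_label(0, "major")))
#' which(v == 1)  # 1, 17, 32: chroma + 1 offset within each 12-unit block
#' @export
encode_melody <- function(m, max_length = 186L) {
  stopifnot(inherits(m, "melody"))
  n <- length(m$chromas)
  if (n < 1L) stop("cannot encode an empty melody", call. = FALSE)
  if (n > max_length) {
    stop(sprintf("melody has %d tones but the input layer holds %d positions",
                 n, max_length), call. = FALSE)
  }
  v <- numeric(12L * max_length)
  v[melody_input_indices(m)] <- 1
  v
}

# 1-based indices of the active input units for a melody
melody_input_indices <- function(m) {
  (seq_along(m$chromas) - 1L) * 12L + m$chromas + 1L
}

#' Encode a key as a 24-bit teacher signal
#'
#' The teacher signal is a 24-bit \{0, 1\} string with a single 1 whose
#' position is the key's index (major keys 0..11 by tonic, minor keys
#' 12..23).
#'
#' @param k a [key_label()].
#' @return Numeric binary vector of length 24.
#' @examples
#' which(encode_key(key_label(9, "minor")) == 1)  # 22 (A minor, index 21)
#' @export
encode_key <- function(k) {
  stopifnot(inherits(k, "key_label"))
  v <- numeric(24L)
  v[k$index + 1L] <- 1
  v
}
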