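#' Tone chromas and key labels
#'
#' Pitch is represented modulo octave as a *tone chroma* (pitch class), an
#' integer in 0..11 with the convention C = 0, C# = 1, ..., B = 11. A *key*
#' is a tonic chroma plus a mode (major or minor); the 24 keys are indexed
#' 0..23 with major keys at `tonic` and minor keys at `12 + tonic`, so
#' index 0 is C major and index 12 is C minor.
#'
#' @param tonic integer tone chroma of the tonic, in 0..11.
#' @param mode `"major"` or `"minor"`.
#' @return An object of class `key_label`: a list with elements `tonic`,
#'   `mode` and the derived `index` in 0..23.
#' @examples
#' key_label(0, "major")        # C major, index 0
#' key_label(9, "minor")$index  # A minor -> 21
#' @export
key_label <- function(tonic, mode = c("major", "minor")) {
  mode <- match.arg(mode)
  if (length(tonic) != 1L || is.na(tonic) || tonic != as.integer(tonic) ||
      tonic < 0L || tonic > 11L) {
    stop("`tonic` must be a single integer tone chroma in 0..11", call. = FALSE)
  }
  tonic <- as.integer(tonic)
  structure(
    list(tonic = tonic, mode = mode,
         index = tonic + if (mode == "minor") 12L else 0L),
    class = "key_label"
  )
}

#' Decode a key index to a key label
#'
#' Inverse of the `index` field of [key_label()]: indices 0..11 are the
#' major keys C..B, indices 12..23 the minor keys C..B.
#'
#' @param index integer in 0..23.
#' @return A `key_label`.
#' @examples
#' decode_key(0)   # C major
#' decode_key(12)  # C minor
#' @export
decode_key <- function(index) {
  if (length(index) != 1L || is.na(index) || index != as.integer(index) ||
      index < 0L || index > 23L) {
    stop("key `index` must be a single integer in 0..23", call. = FALSE)
  }
  index <- as.integer(index)
  key_label(index %% 12L, if (index >= 12L) "minor" else "major")
}

#' @export
print.key_label <- function(x, ...) {
  chroma_names <- c("C", "C#", "D", "D#", "E", "F",
                    "F#", "G", "G#", "A", "A#", "B")
  cat(sprintf("<key> %s %s (index %d)\n",
              chroma_names[x$tonic + 1L], x$mode, x$index))
  invisible(x)
}

#' In-scale degrees of the two modes
#'
#' Scale membership is expressed in tonic-relative degrees (tonic = 0).
#' The major mode uses the diatonic major set \{0, 2, 4, 5, 7, 9, 11\}.
#' The minor mode uses the natural-minor set \{0, 2, 3, 5, 7, 8, 10\}; the
#' raised seventh (degree 11, the harmonic-minor leading tone) is admitted
#' as in-scale by default because it is pervasive in common-practice minor
#' melodies.
#'
#' @param mode `"major"` or `"minor"`.
#' @param raised_seventh logical; count degree 11 as in-scale for the minor
#'   mode (default `TRUE`). Ignored for major.
#' @return Integer vector of in-scale degrees.
#' @export
scale_degrees <- function(mode = c("major", "minor"), raised_seventh = TRUE) {
  mode <- match.arg(mode)
  if (mode == "major") {
    c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  } else {
    d <- c(0L, 2L, 3L, 5L, 7L, 8L, 10L)
    if (raised_seventh) c(d, 11L) else d
  }
}

# run a block under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
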