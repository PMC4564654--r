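#' Read and write melody corpora as JSON Lines
#'
#' One melody per line:
#' `{"id": str, "key": {"tonic": 0-11, "mode": "major"|"minor"}, "chromas": [ints]}`.
#' The format stores melodies only; regeneration parameters travel in the
#' [corpus_spec()], not in the file.
#'
#' @param c a `melody_corpus`.
#' @param path file path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns a `melody_corpus` (with `spec = NULL`).
#' @export
write_corpus_jsonl <- function(c, path) {
  stopifnot(inherits(c, "melody_corpus"))
  lines <- vapply(c$melodies, function(m) {
    jsonlite::toJSON(
      list(id = m$id,
           key = list(tonic = m$key$tonic, mode = m$key$mode),
           chromas = m$chromas),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @param augmented logical flag recorded on the corpus read back.
#' @export
read_corpus_jsonl <- function(path, augmented = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no melodies in ", path, call. = FALSE)
  melodies <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    melody(as.integer(x$chromas),
           key_label(as.integer(x$key$tonic), x$key$mode),
           id = as.character(x$id))
  })
  structure(list(melodies = melodies, spec = NULL, augmented = augmented),
            class = "melody_corpus")
}
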