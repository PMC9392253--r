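#' Circular nucleotide sequence
#'
#' Lightweight container for a circular molecule: id, sequence and optional
#' planted-feature annotations (filled in by the synthetic-data generators).
#'
#' @param seq character string of A/C/G/T
#' @param id molecule identifier
#' @param truth optional data.frame of planted features
#' @return object of class `circular_sequence`
#' @export
circular_sequence <- function(seq, id = "genome", truth = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  structure(
    list(id = id, seq = toupper(seq), length = nchar(seq), truth = truth),
    class = "circular_sequence"
  )
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("<circular_sequence> %s: %d bp", x$id, x$length))
  if (!is.null(x$truth)) cat(sprintf(", %d planted feature(s)", nrow(x$truth)))
  cat("\n")
  invisible(x)
}

#' @export
length.circular_sequence <- function(x) x$length

# Coerce circular_sequence / character to a plain sequence string
#' @keywords internal
as_seq_string <- function(x) {
  if (inherits(x, "circular_sequence")) return(x$seq)
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    return(as.character(x)[1L])
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}
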