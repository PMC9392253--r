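# Low-level sequence machinery shared by the repeat caller, the read
# assignment engine and the synteny-block anchor finder. All coordinates in
# code are 0-based half-open; conversion to 1-based happens only at I/O.

BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integers 0..3
#'
#' Ambiguous characters become NA and are never part of a k-mer seed.
#' @param x single character string
#' @return integer vector (0=A, 1=C, 2=G, 3=T, NA otherwise)
#' @keywords internal
dna_encode <- function(x) {
  v <- utf8ToInt(toupper(x))
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L
  out[v == 67L] <- 1L
  out[v == 71L] <- 2L
  out[v == 84L] <- 3L
  out
}

#' @keywords internal
dna_decode <- function(d) {
  ch <- rep("N", length(d))
  ok <- !is.na(d)
  ch[ok] <- BASES[d[ok] + 1L]
  paste(ch, collapse = "")
}

#' Reverse complement on the integer encoding
#' @keywords internal
dna_revcomp_int <- function(d) rev(3L - d)

#' Reverse complement of a character DNA string
#' @param x character string
#' @return character string
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Rolling k-mer codes
#'
#' Codes are base-4 numbers stored as doubles (exact up to k = 26).
#' Windows containing an ambiguous base get NA.
#' @keywords internal
kmer_codes <- function(d, k) {
  n <- length(d) - k + 1L
  if (n <= 0L) return(numeric(0))
  code <- numeric(n)
  bad <- rep(FALSE, n)
  for (j in seq_len(k)) {
    dj <- d[j:(j + n - 1L)]
    bad <- bad | is.na(dj)
    dj[is.na(dj)] <- 0L
    code <- code * 4 + dj
  }
  code[bad] <- NA_real_
  code
}

#' Extract a (possibly wrapping) arc from a circular sequence
#'
#' @param d integer-encoded sequence
#' @param start 0-based start
#' @param len arc length (must be <= length(d))
#' @keywords internal
circ_sub <- function(d, start, len) {
  L <- length(d)
  stopifnot(len <= L)
  idx <- ((start + seq_len(len) - 1L) %% L) + 1L
  d[idx]
}

#' i.i.d. uniform random DNA (integer encoded)
#' @keywords internal
random_dna_int <- function(n) {
  sample.int(4L, n, replace = TRUE) - 1L
}

#' Mutate a sequence to a target percent identity by random substitutions
#'
#' The number of substituted positions is round(len * (100 - identity)/100);
#' each substitution is to a different base, so realized identity is exact.
#' @keywords internal
mutate_to_identity <- function(d, identity) {
  n_sub <- round(length(d) * (100 - identity) / 100)
  if (n_sub == 0L) return(d)
  pos <- sample.int(length(d), n_sub)
  shift <- sample.int(3L, n_sub, replace = TRUE)
  d[pos] <- (d[pos] + shift) %% 4L
  d
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}
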