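# Repeat census of a single circular mitogenome: self-comparison with exact
# seeds and ungapped X-drop extension, length classification into the four
# standard classes, plastid-derived segment identification, and genome-level
# summaries.

REPEAT_CLASSES <- c("<100", "100-500", "501-1000", ">1000")

#' Detect dispersed repeat pairs in a circular genome
#'
#' Self-comparison by seed-and-extend: exact seeds of length `min_word` are
#' chained along diagonals and extended without gaps under an X-drop rule;
#' alignments are kept when their Karlin-Altschul e-value (genome as both
#' query and subject) is at most `evalue_max`. Both orientations are
#' searched; hits crossing the circular origin are recovered by rescanning a
#' half-length rotation and deduplicating. Mirror duplicates are collapsed
#' to a canonical pair with `startA <= startB`.
#'
#' Coordinates are 0-based half-open on the forward strand; an end beyond
#' the genome length denotes wrap-around across the origin.
#'
#' @param genome `circular_sequence` or character string
#' @param min_word exact seed length (default 7)
#' @param evalue_max e-value ceiling (default 1e-6)
#' @param circular also scan a rotated copy to recover origin-spanning hits
#' @param match,mismatch,xdrop ungapped extension scoring
#' @param max_n_frac error if the fraction of non-ACGT characters exceeds this
#' @return data.frame of class `repeat_pairs` with columns startA, endA,
#'   strandA, startB, endB, strandB, length, identity, class, orientation,
#'   score, evalue, sorted by (startA, startB)
#' @export
find_repeats <- function(genome, min_word = 7L, evalue_max = 1e-6,
                         circular = TRUE, match = 1, mismatch = -2,
                         xdrop = 20, max_n_frac = 0.1) {
  s <- as_seq_string(genome)
  L <- nchar(s)
  stopifnot(L >= 2L * min_word)
  d <- dna_encode(s)
  if (mean(is.na(d)) > max_n_frac) {
    stop("sequence contains more than ", max_n_frac * 100,
         "% non-ACGT characters")
  }

  scan1 <- function(dd, off) {
    cols <- c("sA", "sB", "length", "matches", "score", "orientation")
    # direct: self upper-triangle
    dir_hits <- gapless_hits(dd, dd, word = min_word, self = TRUE,
                             match = match, mismatch = mismatch, xdrop = xdrop)
    dir_hits$orientation <- rep("direct", nrow(dir_hits))
    dir_hits$sA <- dir_hits$aStart
    dir_hits$sB <- dir_hits$bStart
    # inverted: sequence vs its reverse complement, B locus mapped to forward
    rc <- dna_revcomp_int(dd)
    inv_hits <- gapless_hits(dd, rc, word = min_word, self = FALSE,
                             match = match, mismatch = mismatch, xdrop = xdrop)
    inv_hits$orientation <- rep("inverted", nrow(inv_hits))
    inv_hits$sA <- inv_hits$aStart
    inv_hits$sB <- L - inv_hits$bEnd
    h <- rbind(dir_hits[, cols, drop = FALSE], inv_hits[, cols, drop = FALSE])
    if (!nrow(h)) return(h)
    h$sA <- (h$sA + off) %% L
    h$sB <- (h$sB + off) %% L
    h
  }

  hits <- scan1(d, 0L)
  if (circular && L >= 4L) {
    off <- L %/% 2L
    d2 <- c(d[(off + 1L):L], d[1L:off])
    h2 <- scan1(d2, off)
    hits <- rbind(hits, h2)
  }
  if (!nrow(hits)) return(empty_repeat_pairs())

  # drop identical-locus hits (self and palindromic) and canonicalize order
  hits <- hits[hits$sA != hits$sB, , drop = FALSE]
  swap <- hits$sA > hits$sB
  tmp <- hits$sA[swap]; hits$sA[swap] <- hits$sB[swap]; hits$sB[swap] <- tmp

  # significance filter
  hits$evalue <- ka_evalue(hits$score, L, L, match, mismatch)
  hits <- hits[hits$evalue <= evalue_max & hits$length >= min_word, , drop = FALSE]
  if (!nrow(hits)) return(empty_repeat_pairs())

  # circular deduplication: hits on the same (anti)diagonal whose arcs are
  # contained in a longer hit's arcs (in either locus assignment, since the
  # canonical ordering can swap the loci of an origin-spanning fragment)
  # are duplicates from the rotated rescan
  kdir <- (hits$sB - hits$sA) %% L
  key <- ifelse(hits$orientation == "direct",
                pmin(kdir, L - kdir),
                (hits$sA + hits$sB + hits$length) %% L)
  ord <- order(hits$orientation, key, -hits$length)
  hits <- hits[ord, , drop = FALSE]
  key <- key[ord]
  keep <- rep(TRUE, nrow(hits))
  arc_in <- function(sj, lj, si, li) ((sj - si) %% L) + lj <= li
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$orientation == hits$orientation[i] & key == key[i])
    if (!length(j)) next
    straight <- arc_in(hits$sA[j], hits$length[j], hits$sA[i], hits$length[i]) &
      arc_in(hits$sB[j], hits$length[j], hits$sB[i], hits$length[i])
    crossed <- arc_in(hits$sA[j], hits$length[j], hits$sB[i], hits$length[i]) &
      arc_in(hits$sB[j], hits$length[j], hits$sA[i], hits$length[i])
    keep[j[straight | crossed]] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]

  out <- data.frame(
    startA = hits$sA,
    endA = hits$sA + hits$length,
    strandA = "+",
    startB = hits$sB,
    endB = hits$sB + hits$length,
    strandB = ifelse(hits$orientation == "direct", "+", "-"),
    length = hits$length,
    identity = round(100 * hits$matches / hits$length, 2),
    class = classify_repeats(hits$length),
    orientation = hits$orientation,
    score = hits$score,
    evalue = hits$evalue,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

#' @keywords internal
empty_repeat_pairs <- function() {
  out <- data.frame(startA = integer(0), endA = integer(0),
                    strandA = character(0), startB = integer(0),
                    endB = integer(0), strandB = character(0),
                    length = integer(0), identity = numeric(0),
                    class = character(0), orientation = character(0),
                    score = numeric(0), evalue = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

#' Classify repeat lengths into the four standard length classes
#'
#' Bins are closed on integers: `<100`, `100-500` (100 <= length <= 500),
#' `501-1000`, and `>1000` bp.
#'
#' @param x numeric vector of repeat lengths, or a `repeat_pairs` data.frame
#' @return character vector of class labels (levels in `REPEAT_CLASSES` order)
#' @export
classify_repeats <- function(x) {
  if (is.data.frame(x)) x <- x$length
  out <- character(length(x))
  out[x < 100] <- "<100"
  out[x >= 100 & x <= 500] <- "100-500"
  out[x > 500 & x <= 1000] <- "501-1000"
  out[x > 1000] <- ">1000"
  out
}

#' Per-genome repeat summary
#'
#' Counts and total repeat length per length class; each pair is counted
#' once (pair-wise, not per-copy).
#'
#' @param pairs `repeat_pairs` data.frame
#' @param genome `circular_sequence` or character string (for size and GC)
#' @return list with per-class counts, total_count, total_length,
#'   genome_size, gc_content
#' @export
summarize_repeats <- function(pairs, genome) {
  cls <- factor(classify_repeats(pairs), levels = REPEAT_CLASSES)
  counts <- table(cls)
  gs <- genome_stats(genome)
  structure(list(
    class_counts = as.integer(counts),
    class_labels = REPEAT_CLASSES,
    total_count = nrow(pairs),
    total_length = sum(pairs$length),
    genome_size = gs$size,
    gc_content = gs$gc
  ), class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %d pairs, %d bp total (genome %d bp, GC %.2f%%)\n",
              x$total_count, x$total_length, x$genome_size, x$gc_content))
  for (i in seq_along(x$class_labels)) {
    cat(sprintf("  %-9s %d\n", x$class_labels[i], x$class_counts[i]))
  }
  invisible(x)
}

#' Identify plastid-derived segments of a mitogenome
#'
#' The mitogenome is compared against the plastid genome in both
#' orientations with the same seed-and-extend engine used for repeats;
#' significant hit intervals on the mitogenome are unioned.
#'
#' @param mito,plastid `circular_sequence` or character strings
#' @param evalue_max e-value ceiling (default 1e-6)
#' @param word exact seed length (default 7)
#' @return list with `intervals` (data.frame start/end, 0-based half-open on
#'   the mitogenome), `total_bp`, and `percent` of the mitogenome (2 decimals)
#' @export
identify_plastid_derived <- function(mito, plastid, evalue_max = 1e-6, word = 7L) {
  dm <- dna_encode(as_seq_string(mito))
  dp <- dna_encode(as_seq_string(plastid))
  stopifnot(length(dm) > 0L, length(dp) > 0L)
  h1 <- gapless_hits(dm, dp, word = word)
  h2 <- gapless_hits(dm, dna_revcomp_int(dp), word = word)
  hits <- rbind(h1, h2)
  if (nrow(hits)) {
    ev <- ka_evalue(hits$score, length(dm), length(dp))
    hits <- hits[ev <= evalue_max, , drop = FALSE]
  }
  if (!nrow(hits)) {
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                total_bp = 0L, percent = 0))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$aStart + 1L, end = hits$aEnd))
  total <- sum(IRanges::width(ir))
  list(
    intervals = data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir)),
    total_bp = as.integer(total),
    percent = round(100 * total / length(dm), 2)
  )
}

#' Genome size and GC content
#'
#' GC is (G+C)/(A+C+G+T) x 100 over unambiguous bases, 2 decimals.
#'
#' @param genome `circular_sequence` or character string
#' @return list with `size` (bp) and `gc` (percent)
#' @export
genome_stats <- function(genome) {
  d <- dna_encode(as_seq_string(genome))
  ok <- !is.na(d)
  gc <- if (any(ok)) round(100 * mean(d[ok] == 1L | d[ok] == 2L), 2) else NA_real_
  list(size = length(d), gc = gc)
}
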