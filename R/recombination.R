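# Repeat-mediated homologous recombination frequency from long reads.
#
# For a repeat pair (copies b and e with upstream/downstream flanks a,c and
# d,f) the two reference arrangements are a-b-c and d-e-f; crossover
# products exchange flanks across the repeat. Reads aligning with high
# identity and full coverage of both flanking regions vote for one
# arrangement; the recombination frequency is the fraction of informative
# reads supporting a recombinant arrangement.

#' @keywords internal
pair_fields <- function(pair) {
  if (is.data.frame(pair)) pair <- as.list(pair[1L, ])
  stopifnot(all(c("startA", "endA", "startB", "endB") %in% names(pair)))
  if (is.null(pair$orientation)) {
    pair$orientation <- if (!is.null(pair$strandB) && pair$strandB == "-")
      "inverted" else "direct"
  }
  pair
}

# Extract the six assay parts (a,b,c / d,e,f) around a repeat pair with a
# given flank, on the integer encoding; copy e is read in the recombining
# frame (reverse-complemented for inverted pairs).
#' @keywords internal
recomb_parts <- function(d, pair, flank) {
  L <- length(d)
  p <- pair_fields(pair)
  lenA <- p$endA - p$startA
  lenB <- p$endB - p$startB
  a <- circ_sub(d, p$startA - flank, flank)
  b <- circ_sub(d, p$startA, lenA)
  cc <- circ_sub(d, p$endA, flank)
  if (p$orientation == "direct") {
    dd <- circ_sub(d, p$startB - flank, flank)
    e <- circ_sub(d, p$startB, lenB)
    f <- circ_sub(d, p$endB, flank)
  } else {
    e <- dna_revcomp_int(circ_sub(d, p$startB, lenB))
    dd <- dna_revcomp_int(circ_sub(d, p$endB, flank))
    f <- dna_revcomp_int(circ_sub(d, p$startB - flank, flank))
  }
  list(a = a, b = b, c = cc, d = dd, e = e, f = f)
}

#' Build reference and recombinant arrangements for a repeat pair
#'
#' Each repeat copy is extracted with `flank` bp of upstream and downstream
#' context: references are a-b-c and d-e-f. Recombinants are every
#' flank/repeat/flank combination {a,d} x {b,e} x {c,f} minus the two
#' references (six forms); when the two copies are exactly identical the
#' set collapses to the two distinguishable crossover products a-b-f and
#' d-b-c.
#'
#' @param genome `circular_sequence` or character string
#' @param pair repeat pair (row of a `repeat_pairs` data.frame, or list with
#'   startA/endA/startB/endB and orientation)
#' @param flank flank length in bp (default 200)
#' @return object of class `recomb_assay`: forms (named character vector),
#'   form categories (`reference`/`recombinant`), and empty counts
#' @export
build_recombinant_references <- function(genome, pair, flank = 200L) {
  d <- dna_encode(as_seq_string(genome))
  L <- length(d)
  p <- pair_fields(pair)
  gap1 <- (p$startB - p$endA) %% L
  gap2 <- (p$startA - p$endB) %% L
  if (gap1 < flank || gap2 < flank) {
    stop("repeat copies are closer than the flank length; assay undefined")
  }
  parts <- recomb_parts(d, p, flank)
  identical_copies <- length(parts$b) == length(parts$e) &&
    all(parts$b == parts$e)
  cat_ <- function(...) dna_decode(c(...))
  if (identical_copies) {
    forms <- c("a-b-c" = cat_(parts$a, parts$b, parts$c),
               "d-e-f" = cat_(parts$d, parts$e, parts$f),
               "a-b-f" = cat_(parts$a, parts$b, parts$f),
               "d-b-c" = cat_(parts$d, parts$b, parts$c))
    category <- c("reference", "reference", "recombinant", "recombinant")
  } else {
    forms <- c("a-b-c" = cat_(parts$a, parts$b, parts$c),
               "d-e-f" = cat_(parts$d, parts$e, parts$f),
               "a-b-f" = cat_(parts$a, parts$b, parts$f),
               "a-e-c" = cat_(parts$a, parts$e, parts$c),
               "a-e-f" = cat_(parts$a, parts$e, parts$f),
               "d-b-c" = cat_(parts$d, parts$b, parts$c),
               "d-b-f" = cat_(parts$d, parts$b, parts$f),
               "d-e-c" = cat_(parts$d, parts$e, parts$c))
    category <- c("reference", "reference", rep("recombinant", 6L))
  }
  structure(list(
    pair = p, flank = flank, identical_copies = identical_copies,
    forms = forms, category = stats::setNames(category, names(forms)),
    n_ref = NA_integer_, n_recomb = NA_integer_, n_uninformative = NA_integer_,
    frequency = NA_real_, assignments = NULL
  ), class = "recomb_assay")
}

#' @export
print.recomb_assay <- function(x, ...) {
  cat(sprintf("<recomb_assay> repeat %d bp (%s), flank %d bp, %d recombinant form(s)\n",
              x$pair$endA - x$pair$startA, x$pair$orientation, x$flank,
              sum(x$category == "recombinant")))
  if (!is.na(x$n_ref)) {
    cat(sprintf("  reads: %d reference, %d recombinant, %d uninformative; frequency %s%%\n",
                x$n_ref, x$n_recomb, x$n_uninformative,
                ifelse(is.na(x$frequency), "NA", format(round(x$frequency, 2)))))
  }
  invisible(x)
}

# Gap-free local alignment of a read against a form via unique-anchor offset
# voting: shared k-mers vote for a diagonal; the modal diagonal defines the
# alignment; identity and score (match +1 / mismatch -1) are computed over
# the overlap. Returns NULL if no anchors are shared.
#' @keywords internal
anchor_align <- function(dr, form_codes, dform, word) {
  rc_codes <- kmer_codes(dr, word)
  hit <- match(rc_codes, form_codes)
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  off <- hit[ok] - which(ok)           # form index = read index + off
  tb <- table(off)
  off <- as.integer(names(tb)[which.max(tb)])
  Lr <- length(dr); Lf <- length(dform)
  r1 <- max(1L, 1L - off); r2 <- min(Lr, Lf - off)
  if (r2 < r1) return(NULL)
  rr <- dr[r1:r2]; ff <- dform[(r1 + off):(r2 + off)]
  eq <- !is.na(rr) & !is.na(ff) & rr == ff
  nmatch <- sum(eq)
  len <- r2 - r1 + 1L
  list(f1 = r1 + off, f2 = r2 + off, len = len,
       identity = 100 * nmatch / len,
       score = nmatch - (len - nmatch))
}

#' Assign reads to assay forms and count support
#'
#' A read supports a form iff its gap-free local alignment to that form has
#' identity above `min_identity` percent and covers at least
#' `flank_required` bp in each of the two flanking regions. Both read
#' orientations are tried. Reads qualifying for no form are uninformative;
#' among qualifying forms the best alignment score wins, and a score tie
#' across the reference/recombinant categories is uninformative.
#'
#' @param reads character vector (named) or `DNAStringSet` of reads
#' @param assay `recomb_assay` from [build_recombinant_references()]
#' @param min_identity percent identity floor, exclusive (default 99)
#' @param flank_required bp of required coverage in each flank (default 200)
#' @param word anchor k-mer length (default 13)
#' @return the assay with counts, frequency and per-read `assignments` filled
#' @export
assign_reads <- function(reads, assay, min_identity = 99, flank_required = 200L,
                         word = 13L) {
  stopifnot(inherits(assay, "recomb_assay"))
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%05d", seq_along(reads))
  nf <- length(assay$forms)
  dforms <- lapply(assay$forms, dna_encode)
  fcodes <- lapply(dforms, kmer_codes, k = word)
  flank <- assay$flank
  res <- character(length(reads))
  form_of <- character(length(reads))
  for (i in seq_along(reads)) {
    dr1 <- dna_encode(reads[[i]])
    dr2 <- dna_revcomp_int(dr1)
    best_score <- -Inf
    best_cats <- character(0)
    best_form <- NA_character_
    for (j in seq_len(nf)) {
      Lf <- length(dforms[[j]])
      sc <- -Inf
      for (dr in list(dr1, dr2)) {
        al <- anchor_align(dr, fcodes[[j]], dforms[[j]], word)
        if (is.null(al)) next
        cov_up <- max(0L, min(al$f2, flank) - al$f1 + 1L)
        cov_dn <- max(0L, al$f2 - max(al$f1, Lf - flank + 1L) + 1L)
        if (al$identity > min_identity && cov_up >= flank_required &&
            cov_dn >= flank_required) {
          sc <- max(sc, al$score)
        }
      }
      if (!is.finite(sc)) next
      if (sc > best_score) {
        best_score <- sc
        best_cats <- assay$category[[j]]
        best_form <- names(assay$forms)[j]
      } else if (sc == best_score) {
        best_cats <- union(best_cats, assay$category[[j]])
      }
    }
    if (!length(best_cats) || length(best_cats) > 1L) {
      res[i] <- "uninformative"
      form_of[i] <- NA_character_
    } else {
      res[i] <- best_cats
      form_of[i] <- best_form
    }
  }
  assay$assignments <- data.frame(read = names(reads), category = res,
                                  form = form_of, stringsAsFactors = FALSE)
  assay$n_ref <- sum(res == "reference")
  assay$n_recomb <- sum(res == "recombinant")
  assay$n_uninformative <- sum(res == "uninformative")
  assay$frequency <- recombination_frequency(assay)
  assay
}

#' Recombination frequency of an assay
#'
#' 100 x n_recomb / (n_ref + n_recomb); NA when no informative reads.
#' Uninformative reads are excluded from the denominator.
#'
#' @param assay `recomb_assay` with counts, or a list with n_ref and n_recomb
#' @return percent in `[0, 100]`, or NA
#' @export
recombination_frequency <- function(assay) {
  denom <- assay$n_ref + assay$n_recomb
  if (is.na(denom) || denom == 0L) return(NA_real_)
  100 * assay$n_recomb / denom
}

#' Filter a read set down to mitochondrial reads
#'
#' Keeps reads with a mitochondrial alignment at e-value at most
#' `evalue_max` and drops reads whose plastid alignments cover more than
#' `plastid_cov_max` of the read length.
#'
#' @param reads named character vector or `DNAStringSet`
#' @param mito_ref,plastid_ref reference sequences
#' @param evalue_max mitochondrial hit e-value ceiling (default 1e-100)
#' @param plastid_cov_max maximum tolerated plastid coverage fraction (0.85)
#' @param word seed length for read mapping (default 11)
#' @return filtered reads (same type), with a `filter_stats` attribute
#' @export
build_mito_read_set <- function(reads, mito_ref, plastid_ref,
                                evalue_max = 1e-100, plastid_cov_max = 0.85,
                                word = 11L) {
  was_set <- inherits(reads, "DNAStringSet")
  if (was_set) reads <- as.character(reads)
  if (!length(reads)) {
    warning("empty read set")
    return(reads)
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%05d", seq_along(reads))
  dm <- dna_encode(as_seq_string(mito_ref))
  dp <- dna_encode(as_seq_string(plastid_ref))
  keep <- logical(length(reads))
  cov <- numeric(length(reads))
  for (i in seq_along(reads)) {
    dr <- dna_encode(reads[[i]])
    lr <- length(dr)
    best <- -Inf
    for (dd in list(dr, dna_revcomp_int(dr))) {
      h <- gapless_hits(dd, dm, word = word, xdrop = 40)
      if (nrow(h)) best <- max(best, max(h$score))
    }
    mito_ok <- is.finite(best) &&
      ka_evalue(best, lr, length(dm)) <= evalue_max
    # plastid coverage: union of read intervals over both orientations
    ivs <- list()
    for (ori in 1:2) {
      dd <- if (ori == 1L) dr else dna_revcomp_int(dr)
      h <- gapless_hits(dd, dp, word = word, xdrop = 40)
      if (!nrow(h)) next
      h <- h[ka_evalue(h$score, lr, length(dp)) <= 1e-6, , drop = FALSE]
      if (!nrow(h)) next
      s <- h$aStart; e <- h$aEnd
      if (ori == 2L) { s2 <- lr - h$aEnd; e2 <- lr - h$aStart; s <- s2; e <- e2 }
      ivs[[length(ivs) + 1L]] <- cbind(s, e)
    }
    if (length(ivs)) {
      iv <- do.call(rbind, ivs)
      ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L]))
      cov[i] <- sum(IRanges::width(ir)) / lr
    }
    keep[i] <- mito_ok && cov[i] <= plastid_cov_max
  }
  out <- reads[keep]
  attr(out, "filter_stats") <- data.frame(read = names(reads),
                                          plastid_cov = cov, kept = keep)
  if (was_set) out <- Biostrings::DNAStringSet(out)
  out
}

#' Recombination activity summary across repeat pairs
#'
#' A pair is active when it has at least `min_support` recombinant-supporting
#' reads. Summaries follow the standard four repeat length classes, with
#' additional counts of active pairs in low (<1 percent), high (>20) and
#' very high (>50) frequency bands.
#'
#' @param assays data.frame with columns `class`, `n_recomb` and `frequency`
#'   (one row per assayed repeat pair), or a list of `recomb_assay` objects
#' @param min_support minimum recombinant reads to call a pair active
#' @return object of class `activity_summary`: per-class data.frame
#'   (n_total, n_active, percent_active) and frequency band counts
#' @export
activity_summary <- function(assays, min_support = 1L) {
  if (!is.data.frame(assays)) {
    assays <- do.call(rbind, lapply(assays, function(a) {
      data.frame(class = classify_repeats(a$pair$endA - a$pair$startA),
                 n_recomb = a$n_recomb, frequency = a$frequency,
                 stringsAsFactors = FALSE)
    }))
  }
  cls <- factor(assays$class, levels = REPEAT_CLASSES)
  active <- !is.na(assays$n_recomb) & assays$n_recomb >= min_support
  n_total <- as.integer(table(cls))
  n_active <- as.integer(table(cls[active]))
  per_class <- data.frame(
    class = REPEAT_CLASSES,
    n_total = n_total,
    n_active = n_active,
    percent_active = ifelse(n_total > 0, round(100 * n_active / n_total, 2), NA)
  )
  fr <- assays$frequency[active]
  fr <- fr[!is.na(fr)]
  structure(list(
    per_class = per_class,
    n_total = nrow(assays),
    n_active = sum(active),
    percent_active = round(100 * sum(active) / nrow(assays), 2),
    bands = c(below_1 = sum(fr < 1), above_20 = sum(fr > 20),
              above_50 = sum(fr > 50))
  ), class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> %d / %d pairs active (%.2f%%)\n",
              x$n_active, x$n_total, x$percent_active))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  frequency bands: <1%%: %d, >20%%: %d, >50%%: %d\n",
              x$bands["below_1"], x$bands["above_20"], x$bands["above_50"]))
  invisible(x)
}
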