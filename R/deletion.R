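# Depth-ratio genotyping of large deletions: the mean read depth over a
# candidate region (Idep) divided by the whole-genome depth (Wdep)
# classifies each accession as carrying or lacking the region; carrier
# frequencies are compared between groups by Pearson chi-square.

#' Depth ratio of a candidate region
#'
#' @param depths per-base depths over the region, or a single precomputed
#'   region mean
#' @param wdep whole-genome mean depth
#' @param method "mean" (default) or "median" region summary
#' @return Idep / Wdep, NA when Wdep is 0
#' @export
depth_ratio <- function(depths, wdep, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(all(depths >= 0, na.rm = TRUE), wdep >= 0)
  idep <- if (length(depths) == 1L) depths else
    switch(method, mean = mean(depths, na.rm = TRUE),
           median = stats::median(depths, na.rm = TRUE))
  if (wdep == 0) return(NA_real_)
  idep / wdep
}

#' Classify region presence from a depth ratio
#'
#' Single-threshold mode calls the region present when ratio >= `threshold`
#' (default 2, near the log-midpoint of the empirical bands). Two-band mode
#' preserves the empirical gap: ratios at or below the low-band ceiling are
#' absent, at or above the high-band floor present, and anything strictly
#' between is ambiguous.
#'
#' @param ratio numeric vector of depth ratios
#' @param threshold single-threshold cutoff (default 2.0)
#' @param mode "threshold" (default) or "bands"
#' @param bands c(low_max, high_min) band edges for two-band mode
#' @return character vector: "present", "absent", "ambiguous" (NA in, NA out)
#' @export
classify_presence <- function(ratio, threshold = 2.0,
                              mode = c("threshold", "bands"),
                              bands = c(0.72, 6.94)) {
  mode <- match.arg(mode)
  out <- rep(NA_character_, length(ratio))
  ok <- !is.na(ratio)
  if (mode == "threshold") {
    out[ok] <- ifelse(ratio[ok] >= threshold, "present", "absent")
  } else {
    out[ok & ratio <= bands[1L]] <- "absent"
    out[ok & ratio >= bands[2L]] <- "present"
    out[ok & ratio > bands[1L] & ratio < bands[2L]] <- "ambiguous"
  }
  out
}

#' Pearson chi-square for a 2x2 table (closed form)
#' @keywords internal
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  N <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  if (m == 0) return(c(chi2 = NA_real_, p = NA_real_))
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / m
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Carrier frequencies per group with chi-square comparisons
#'
#' Per-group presence percentages, an overall Pearson chi-square over the
#' groups-by-presence table, and pairwise 2x2 chi-square tests (no
#' continuity correction by default).
#'
#' @param calls character vector of presence calls ("present"/"absent";
#'   ambiguous and NA calls are dropped), named by sample, or a data.frame
#'   with columns sample and call
#' @param group_map named character vector sample -> group
#' @param yates apply the continuity correction in the pairwise tests
#' @return object of class `carrier_table`: per-group data.frame, overall
#'   chi2/p_value, pairwise data.frame
#' @export
carrier_frequencies <- function(calls, group_map, yates = FALSE) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$call, calls$sample)
  }
  keep <- !is.na(calls) & calls %in% c("present", "absent")
  calls <- calls[keep]
  grp <- group_map[names(calls)]
  groups <- sort(unique(grp))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    cg <- calls[grp == g]
    np <- sum(cg == "present")
    data.frame(group = g, n_present = np, n_total = length(cg),
               percent = round(100 * np / length(cg), 2),
               stringsAsFactors = FALSE)
  }))
  # overall Pearson chi-square on the G x 2 table
  tab <- rbind(per_group$n_present, per_group$n_total - per_group$n_present)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(E > 0)) {
    chi2 <- sum((tab - E)^2 / E)
    p <- stats::pchisq(chi2, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
                       lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  pw <- NULL
  if (length(groups) >= 2L) {
    cmb <- utils::combn(seq_along(groups), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      x <- chi2_2x2(per_group$n_present[i],
                    per_group$n_total[i] - per_group$n_present[i],
                    per_group$n_present[j],
                    per_group$n_total[j] - per_group$n_present[j],
                    yates = yates)
      data.frame(groupA = groups[i], groupB = groups[j],
                 chi2 = unname(x["chi2"]), p_value = unname(x["p"]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_group = per_group, chi2 = chi2, p_value = p,
                 pairwise = pw), class = "carrier_table")
}

#' @export
print.carrier_table <- function(x, ...) {
  cat("<carrier_table>\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf("  overall chi2 = %.4g, p = %.3g\n", x$chi2, x$p_value))
  invisible(x)
}

#' Union of homology hit intervals
#'
#' Hits shorter than `min_hit_len` are discarded; the rest are unioned into
#' non-overlapping intervals. Output is invariant to hit order and
#' duplication.
#'
#' @param hits data.frame with columns start, end (0-based half-open on the
#'   target region)
#' @param region_length optional region length for the percent
#' @param min_hit_len minimum hit length kept (default 100 bp)
#' @return list: intervals (data.frame start, end), total_bp, percent (or NA)
#' @export
merge_homology_hits <- function(hits, region_length = NULL, min_hit_len = 100L) {
  hits <- hits[(hits$end - hits$start) >= min_hit_len, , drop = FALSE]
  if (!nrow(hits)) {
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                total_bp = 0L,
                percent = if (is.null(region_length)) NA_real_ else 0))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$start + 1L, end = hits$end))
  total <- as.integer(sum(IRanges::width(ir)))
  list(
    intervals = data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir)),
    total_bp = total,
    percent = if (is.null(region_length)) NA_real_ else
      round(100 * total / region_length, 2)
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a sequence for open reading frames
#'
#' Both strands, three frames each: every ATG is paired with its nearest
#' in-frame downstream stop codon; ORFs of at least `min_len` bp (start
#' through stop inclusive) are reported, including nested/overlapping ones.
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param sequence character string or `circular_sequence` (treated as
#'   linear, as for an excised deletion region)
#' @param min_len minimum ORF length in bp, stop codon included (default 150)
#' @return data.frame start, end, strand, frame, length
#' @export
orf_scan <- function(sequence, min_len = 150L) {
  s <- as_seq_string(sequence)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < 2L) next
      starts0 <- frame + 3L * (seq_len(ncod) - 1L)           # 0-based codon starts
      cod <- substring(ss, starts0 + 1L, starts0 + 3L)
      atg <- which(cod == "ATG")
      stp <- which(cod %in% STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      nxt <- stp[findInterval(atg, stp) + 1L]                # nearest stop after ATG
      ok <- !is.na(nxt)
      atg <- atg[ok]; nxt <- nxt[ok]
      if (!length(atg)) next
      len <- (nxt - atg + 1L) * 3L
      ok <- len >= min_len
      atg <- atg[ok]; nxt <- nxt[ok]; len <- len[ok]
      if (!length(atg)) next
      s0 <- starts0[atg]; e0 <- starts0[nxt] + 3L            # on scanned strand
      if (strand == "-") {
        tmp <- L - e0; e0 <- L - s0; s0 <- tmp
      }
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0, strand = strand, frame = frame,
        length = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
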