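# Windowed diversity and differentiation on haploid variant matrices from a
# circular reference: site filtering (MAF, missingness), per-window
# nucleotide diversity, the Weir-Cockerham F_ST estimator specialized to
# haploid calls, and the sweep rule (F_ST and pi-ratio thresholds).

#' Haploid variant matrix
#'
#' @param gt integer matrix, sites x samples; 0 = reference allele, 1.. =
#'   alternate alleles, NA = missing
#' @param pos 1-based, strictly increasing site positions on the circle
#' @param pops named character vector: sample id -> population label;
#'   names must match `colnames(gt)`
#' @param ref_len reference circle length in bp
#' @return object of class `variant_matrix`
#' @export
variant_matrix <- function(gt, pos, pops, ref_len) {
  stopifnot(is.matrix(gt), nrow(gt) == length(pos))
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (is.null(colnames(gt))) colnames(gt) <- names(pops)
  stopifnot(setequal(colnames(gt), names(pops)))
  pops <- pops[colnames(gt)]
  structure(list(gt = gt, pos = as.integer(pos), pops = pops,
                 ref_len = as.integer(ref_len)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d site(s) x %d haploid sample(s), circle %d bp\n",
              nrow(x$gt), ncol(x$gt), x$ref_len))
  print(table(x$pops))
  invisible(x)
}

#' Filter sites on minor allele frequency and missingness
#'
#' Keeps sites with MAF strictly above `maf_min` (computed over non-missing
#' haploid calls; MAF is the frequency of the second most common allele)
#' and missing fraction strictly below `max_missing`.
#'
#' @param vm `variant_matrix`
#' @param maf_min MAF floor (default 0.01, exclusive)
#' @param max_missing missing-fraction ceiling (default 0.1, exclusive)
#' @return filtered `variant_matrix` (site order preserved)
#' @export
filter_variants <- function(vm, maf_min = 0.01, max_missing = 0.1) {
  gt <- vm$gt
  ns <- ncol(gt)
  miss <- rowMeans(is.na(gt))
  maf <- apply(gt, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(0)
    f <- sort(tabulate(g + 1L, nbins = max(g) + 1L) / length(g),
              decreasing = TRUE)
    if (length(f) < 2L) 0 else f[2L]
  })
  keep <- maf > maf_min & miss < max_missing
  variant_matrix(gt[keep, , drop = FALSE], vm$pos[keep], vm$pops, vm$ref_len)
}

# Per-site nucleotide diversity (unbiased): (n/(n-1)) * (1 - sum p_a^2)
#' @keywords internal
site_pi <- function(gt_sub) {
  apply(gt_sub, 1L, function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    if (n < 2L) return(0)
    p <- tabulate(g + 1L, nbins = max(g) + 1L) / n
    n / (n - 1) * (1 - sum(p^2))
  })
}

# Window starts tiling the circle at the given step
#' @keywords internal
window_starts <- function(ref_len, window, step) {
  seq(1L, ref_len, by = step)
}

# Sum per-site values into circular windows
#' @keywords internal
window_sum <- function(pos, val, ref_len, window, step) {
  starts <- window_starts(ref_len, window, step)
  vapply(starts, function(s) {
    inwin <- ((pos - s) %% ref_len) < window
    sum(val[inwin])
  }, numeric(1))
}

#' Sliding-window nucleotide diversity
#'
#' Per-site pi is the mean pairwise difference among non-missing haploid
#' calls; window pi is the sum over contained sites divided by the window
#' length (per-bp). Windows tile the circle (default 1000 bp windows, 500
#' bp step) and wrap across the origin.
#'
#' @param vm `variant_matrix`
#' @param pop population label (of `vm$pops`) to restrict to
#' @param window,step window and step in bp
#' @return data.frame start, end (1-based; end may exceed the circle length
#'   for wrapping windows), n_sites, pi
#' @export
windowed_pi <- function(vm, pop, window = 1000L, step = 500L) {
  sel <- vm$pops == pop
  if (!any(sel)) stop("no samples in population '", pop, "'")
  ps <- site_pi(vm$gt[, sel, drop = FALSE])
  starts <- window_starts(vm$ref_len, window, step)
  data.frame(
    start = starts,
    end = starts + window - 1L,
    n_sites = window_sum(vm$pos, rep(1, length(vm$pos)), vm$ref_len, window, step),
    pi = window_sum(vm$pos, ps, vm$ref_len, window, step) / window
  )
}

# Weir-Cockerham variance components for one site, haploid specialization
# (individuals are alleles; no heterozygosity term). Returns c(a, a+b)
# summed over alleles, or NULL if undefined.
#' @keywords internal
site_wc_components <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) return(NULL)
  alleles <- sort(unique(c(g1, g2)))
  if (length(alleles) < 2L) return(c(0, 0))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  a_sum <- 0; ab_sum <- 0
  for (al in alleles) {
    p1 <- mean(g1 == al); p2 <- mean(g2 == al)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
    a_sum <- a_sum + a
    ab_sum <- ab_sum + a + b
  }
  c(a_sum / 2, ab_sum / 2)  # each allele pair counted twice for biallelic symmetry
}

#' Sliding-window Weir-Cockerham F_ST (haploid)
#'
#' The weighted estimator: theta = sum(a) / sum(a+b) over sites in each
#' window, with the haploid specialization of the Weir-Cockerham variance
#' components (no within-individual term). Negative window estimates are
#' reported as computed, not truncated.
#'
#' @param vm `variant_matrix`
#' @param popA,popB population labels
#' @param window,step window and step in bp
#' @return data.frame start, end, n_sites, fst (NA where undefined)
#' @export
windowed_fst <- function(vm, popA, popB, window = 1000L, step = 500L) {
  sA <- vm$pops == popA
  sB <- vm$pops == popB
  if (!any(sA) || !any(sB)) stop("population label not found")
  comp <- lapply(seq_len(nrow(vm$gt)), function(i) {
    site_wc_components(vm$gt[i, sA], vm$gt[i, sB])
  })
  ok <- !vapply(comp, is.null, logical(1))
  a <- vapply(comp[ok], `[`, numeric(1), 1L)
  ab <- vapply(comp[ok], `[`, numeric(1), 2L)
  pos <- vm$pos[ok]
  starts <- window_starts(vm$ref_len, window, step)
  a_w <- window_sum(pos, a, vm$ref_len, window, step)
  ab_w <- window_sum(pos, ab, vm$ref_len, window, step)
  data.frame(
    start = starts,
    end = starts + window - 1L,
    n_sites = window_sum(pos, rep(1, length(pos)), vm$ref_len, window, step),
    fst = ifelse(ab_w > 0, a_w / ab_w, NA_real_)
  )
}

#' Combined per-window sweep statistics
#'
#' Convenience wrapper returning one row per window with pi for both
#' populations, F_ST, the pi ratio (wild over cultivated) and the sweep
#' flag at the given thresholds.
#'
#' @param vm `variant_matrix`
#' @param wild,cul population labels for the wild and cultivated groups
#' @param window,step window and step in bp
#' @param fst_min,ratio_min sweep thresholds (exclusive)
#' @param allow_infinite_ratio flag windows with pi_cul = 0 < pi_wild as
#'   infinite-ratio sweeps (default FALSE: ratio is NA, never flagged)
#' @return data.frame start, end, pi_wild, pi_cul, fst, ratio, sweep
#' @export
window_stats <- function(vm, wild = "wild", cul = "cultivated",
                         window = 1000L, step = 500L,
                         fst_min = 0.1, ratio_min = 2.0,
                         allow_infinite_ratio = FALSE) {
  pw <- windowed_pi(vm, wild, window, step)
  pc <- windowed_pi(vm, cul, window, step)
  fs <- windowed_fst(vm, wild, cul, window, step)
  ratio <- ifelse(pc$pi > 0, pw$pi / pc$pi,
                  ifelse(allow_infinite_ratio & pw$pi > 0, Inf, NA_real_))
  sweep <- !is.na(fs$fst) & !is.na(ratio) & fs$fst > fst_min & ratio > ratio_min
  data.frame(
    start = pw$start, end = pw$end,
    pi_wild = pw$pi, pi_cul = pc$pi,
    fst = fs$fst, ratio = ratio, sweep = sweep
  )
}

#' Call sweep regions from flagged windows
#'
#' A window is flagged iff F_ST > `fst_min` and pi_wild/pi_cul > `ratio_min`;
#' overlapping or adjacent flagged windows are merged into regions. A pair
#' of regions touching the two sides of the circular origin is merged into
#' one wrapping region.
#'
#' @param windows data.frame as returned by [window_stats()] (columns start,
#'   end, fst, ratio); an existing `sweep` column is ignored and recomputed
#' @param fst_min,ratio_min thresholds (exclusive)
#' @param ref_len circle length; defaults to max window end (no wrap merge
#'   if unknown)
#' @return data.frame of regions: start, end, n_windows, span_bp
#' @export
call_sweeps <- function(windows, fst_min = 0.1, ratio_min = 2.0, ref_len = NULL) {
  flag <- !is.na(windows$fst) & !is.na(windows$ratio) &
    windows$fst > fst_min & windows$ratio > ratio_min
  w <- windows[flag, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0), span_bp = integer(0))
  if (!nrow(w)) return(empty)
  w <- w[order(w$start), , drop = FALSE]
  rs <- w$start[1L]; re <- w$end[1L]; nw <- 1L
  out <- list()
  if (nrow(w) > 1L) {
    for (i in 2L:nrow(w)) {
      if (w$start[i] <= re + 1L) {
        re <- max(re, w$end[i]); nw <- nw + 1L
      } else {
        out[[length(out) + 1L]] <- c(rs, re, nw)
        rs <- w$start[i]; re <- w$end[i]; nw <- 1L
      }
    }
  }
  out[[length(out) + 1L]] <- c(rs, re, nw)
  reg <- do.call(rbind, out)
  reg <- data.frame(start = reg[, 1L], end = reg[, 2L], n_windows = reg[, 3L])
  # circular wrap: last region reaching past the origin joins the first
  if (!is.null(ref_len) && nrow(reg) > 1L) {
    lastw <- nrow(reg)
    if (reg$end[lastw] >= ref_len && reg$start[1L] == 1L) {
      wrap_end <- reg$end[1L] + ref_len
      reg$end[lastw] <- max(reg$end[lastw], wrap_end)
      reg$n_windows[lastw] <- reg$n_windows[lastw] + reg$n_windows[1L]
      reg <- reg[-1L, , drop = FALSE]
    }
  }
  reg$span_bp <- reg$end - reg$start + 1L
  rownames(reg) <- NULL
  reg
}
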