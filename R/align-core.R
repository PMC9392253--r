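# Gap-free seed-and-extend alignment engine.
#
# Exact k-mer seeds are grouped by diagonal, chained, and extended in both
# directions with an X-drop rule; significance is scored with the
# Karlin-Altschul statistic E = K * m * n * exp(-lambda * S). Extension is
# substitution-only (single diagonal), which is exact for the divergence
# model used throughout the package (point substitutions, no indels).

KA_K <- 0.35  # Karlin-Altschul prefactor, fixed; lambda is solved per score scheme

#' Karlin-Altschul lambda for a match/mismatch scheme on uniform base composition
#' @keywords internal
ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Karlin-Altschul e-value of an ungapped score
#' @keywords internal
ka_evalue <- function(score, m, n, match = 1, mismatch = -2) {
  lambda <- ka_lambda(match, mismatch)
  KA_K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

# All exact-seed pairs between two encoded sequences. Returns 0-based
# positions. self=TRUE restricts to i < j (upper triangle, no self-hits).
# Codes occurring more than max_occ times on either side are skipped
# (low-complexity guard, as seed-occupancy caps in BLAST-family tools).
#' @keywords internal
seed_pairs <- function(ca, cb, self = FALSE, max_occ = 64L) {
  pa <- which(!is.na(ca))
  va <- ca[pa]
  if (self) {
    pb <- pa
    vb <- va
  } else {
    pb <- which(!is.na(cb))
    vb <- cb[pb]
  }
  fa <- factor(va)
  fb <- factor(vb, levels = levels(fa))
  ka <- tabulate(fa, nbins = nlevels(fa))
  kb <- tabulate(fb, nbins = nlevels(fa))
  need <- if (self) 2L else 1L
  good <- ka >= need & kb >= 1L & ka <= max_occ & kb <= max_occ
  if (!any(good)) return(list(I = integer(0), J = integer(0)))
  keep_a <- good[as.integer(fa)]
  keep_b <- good[as.integer(fb)]
  pa <- pa[keep_a]; fa2 <- as.integer(fa)[keep_a]
  pb <- pb[keep_b]; fb2 <- as.integer(fb)[keep_b]
  oa <- order(fa2, pa); pa <- pa[oa]; fa2 <- fa2[oa]
  ob <- order(fb2, pb); pb <- pb[ob]; fb2 <- fb2[ob]

  if (self) {
    # pairs i < j within each code group
    runs <- rle(fa2)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    I <- vector("list", length(runs$lengths))
    J <- vector("list", length(runs$lengths))
    for (g in seq_along(runs$lengths)) {
      f <- runs$lengths[g]
      pos <- pa[starts[g]:ends[g]]
      if (f == 2L) {
        I[[g]] <- pos[1L]; J[[g]] <- pos[2L]
      } else {
        cmb <- utils::combn(pos, 2L)
        I[[g]] <- cmb[1L, ]; J[[g]] <- cmb[2L, ]
      }
    }
    list(I = unlist(I) - 1L, J = unlist(J) - 1L)
  } else {
    ra <- rle(fa2); rb <- rle(fb2)
    enda <- cumsum(ra$lengths); starta <- enda - ra$lengths + 1L
    endb <- cumsum(rb$lengths); startb <- endb - rb$lengths + 1L
    # ra and rb run over the same ordered code ids but may miss levels
    mb <- match(ra$values, rb$values)
    I <- vector("list", length(ra$values))
    J <- vector("list", length(ra$values))
    for (g in seq_along(ra$values)) {
      h <- mb[g]
      if (is.na(h)) next
      posa <- pa[starta[g]:enda[g]]
      posb <- pb[startb[h]:endb[h]]
      na <- length(posa); nb <- length(posb)
      I[[g]] <- rep(posa, each = nb)
      J[[g]] <- rep(posb, times = na)
    }
    list(I = unlist(I) - 1L, J = unlist(J) - 1L)
  }
}

# X-drop ungapped extension of many candidates in lockstep.
# aFrom/bFrom: 0-based position of the first base examined (dir = +1 right,
# dir = -1 left). Returns per-candidate extension length, score gain and
# match count at the best prefix.
#' @keywords internal
xdrop_extend <- function(dA, dB, aFrom, bFrom, dir, xdrop = 20, match = 1, mismatch = -2) {
  m <- length(aFrom)
  best <- numeric(m); bestext <- integer(m); bestmat <- integer(m)
  cur <- numeric(m); curmat <- integer(m)
  active <- seq_len(m)
  La <- length(dA); Lb <- length(dB)
  t <- 0L
  while (length(active)) {
    pa <- aFrom[active] + dir * t
    pb <- bFrom[active] + dir * t
    ok <- pa >= 0L & pa < La & pb >= 0L & pb < Lb
    ba <- dA[pa[ok] + 1L]; bb <- dB[pb[ok] + 1L]
    eq <- !is.na(ba) & !is.na(bb) & ba == bb
    okidx <- active[ok]
    cur[okidx] <- cur[okidx] + ifelse(eq, match, mismatch)
    curmat[okidx] <- curmat[okidx] + as.integer(eq)
    imp <- okidx[cur[okidx] > best[okidx]]
    best[imp] <- cur[imp]
    bestext[imp] <- t + 1L
    bestmat[imp] <- curmat[imp]
    dead <- cur[okidx] <= best[okidx] - xdrop
    active <- okidx[!dead]
    t <- t + 1L
  }
  list(ext = bestext, gain = best, matches = bestmat)
}

# Chain seeds along diagonals, extend, and score. Returns a data.frame of
# gap-free local alignments with 0-based half-open coordinates on A and B.
#' @keywords internal
gapless_hits <- function(dA, dB, word, self = FALSE, merge_gap = 60L,
                         xdrop = 20, match = 1, mismatch = -2, max_occ = 64L) {
  empty <- data.frame(aStart = integer(0), aEnd = integer(0),
                      bStart = integer(0), bEnd = integer(0),
                      length = integer(0), matches = integer(0),
                      score = numeric(0))
  ca <- kmer_codes(dA, word)
  cb <- if (self) ca else kmer_codes(dB, word)
  sp <- seed_pairs(ca, cb, self = self, max_occ = max_occ)
  if (!length(sp$I)) return(empty)
  I <- sp$I; J <- sp$J
  dg <- J - I
  o <- order(dg, I)
  I <- I[o]; J <- J[o]; dg <- dg[o]
  newrun <- c(TRUE, dg[-1L] != dg[-length(dg)] |
                (I[-1L] - I[-length(I)]) > merge_gap)
  grp <- cumsum(newrun)
  run_first <- which(newrun)
  run_last <- c(run_first[-1L] - 1L, length(I))
  aStart <- I[run_first]
  bStart <- J[run_first]
  aEnd <- I[run_last] + word  # half-open

  # interior (seed-chained span) score
  lens <- aEnd - aStart
  gidx <- rep.int(seq_along(lens), lens)
  ia <- sequence(lens) - 1L + rep.int(aStart, lens)
  ib <- sequence(lens) - 1L + rep.int(bStart, lens)
  eq <- !is.na(dA[ia + 1L]) & !is.na(dB[ib + 1L]) & dA[ia + 1L] == dB[ib + 1L]
  mat <- as.integer(rowsum(as.numeric(eq), gidx))
  score <- mat * match + (lens - mat) * mismatch

  extR <- xdrop_extend(dA, dB, aEnd, bStart + lens, +1L, xdrop, match, mismatch)
  extL <- xdrop_extend(dA, dB, aStart - 1L, bStart - 1L, -1L, xdrop, match, mismatch)

  out <- data.frame(
    aStart = aStart - extL$ext,
    aEnd = aEnd + extR$ext,
    bStart = bStart - extL$ext,
    bEnd = bStart + lens + extR$ext,
    length = lens + extL$ext + extR$ext,
    matches = mat + extL$matches + extR$matches,
    score = score + extL$gain + extR$gain
  )
  # deduplicate identical extended alignments (seeds of one repeat converge)
  key <- paste(out$aEnd - out$bEnd, out$aStart, out$aEnd)
  out <- out[!duplicated(key), , drop = FALSE]
  # drop alignments contained in a longer one on the same diagonal
  dgo <- out$bStart - out$aStart
  o <- order(dgo, out$aStart, -out$length)
  out <- out[o, , drop = FALSE]
  dgo <- dgo[o]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L) {
    maxend <- out$aEnd[1L]
    for (i in 2L:nrow(out)) {
      if (dgo[i] == dgo[i - 1L] && out$aStart[i] >= out$aStart[i - 1L] &&
          out$aEnd[i] <= maxend) {
        keep[i] <- FALSE
      }
      if (dgo[i] != dgo[i - 1L]) maxend <- out$aEnd[i] else
        maxend <- max(maxend, out$aEnd[i])
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
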