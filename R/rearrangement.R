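# Genome rearrangement: exact minimum inversion distance for circular
# signed block orders (Hannenhalli-Pevzner breakpoint-graph theory with
# hurdle and fortress corrections), synteny blocks from unique shared
# anchors, and conversion of event counts to rates on dated phylogenies.

#' Signed circular block order
#'
#' @param blocks integer vector of signed block ids; absolute values must be
#'   a permutation of 1..n
#' @param genome_id identifier
#' @return object of class `signed_perm`
#' @export
signed_perm <- function(blocks, genome_id = "genome") {
  blocks <- as.integer(blocks)
  n <- length(blocks)
  if (n < 1L || any(blocks == 0L) || !setequal(abs(blocks), seq_len(n))) {
    stop("blocks must be signed integers whose absolute values are a permutation of 1..n")
  }
  structure(list(blocks = blocks, n = n, genome_id = genome_id),
            class = "signed_perm")
}

#' @export
print.signed_perm <- function(x, ...) {
  cat(sprintf("<signed_perm> %s (circular, %d blocks): %s\n", x$genome_id,
              x$n, paste(x$blocks, collapse = " ")))
  invisible(x)
}

#' @keywords internal
perm_blocks <- function(p) {
  if (inherits(p, "signed_perm")) p$blocks else as.integer(p)
}

#' Canonical linearization of a circular signed permutation
#'
#' Reflects (reverse order, flip signs) if block 1 carries a minus sign,
#' then rotates so +1 leads. Two circular orders are the same genome iff
#' their canonical forms are identical.
#'
#' @param p `signed_perm` or signed integer vector
#' @return integer vector starting with +1
#' @export
canonicalize_perm <- function(p) {
  p <- perm_blocks(p)
  i <- which(abs(p) == 1L)
  if (length(i) != 1L) stop("malformed permutation: block 1 not unique")
  if (p[i] < 0L) {
    p <- -rev(p)
    i <- which(abs(p) == 1L)
  }
  if (i > 1L) p <- c(p[i:length(p)], p[seq_len(i - 1L)])
  p
}

#' Minimum inversion distance of a circular signed permutation
#'
#' Exact minimum number of inversions sorting the circular order to the
#' circular identity, computed by reducing to the linear problem (fix block
#' 1) and applying the Hannenhalli-Pevzner formula
#' d = b - c + h + f over the breakpoint graph (b black edges, c cycles,
#' h hurdles, f fortress indicator).
#'
#' @param perm `signed_perm` or signed integer vector (circular order)
#' @return integer distance
#' @export
inversion_distance <- function(perm) {
  p <- canonicalize_perm(perm)
  n <- length(p)
  if (n <= 1L) return(0L)
  q <- p[-1L]
  q <- as.integer(sign(q) * (abs(q) - 1L))
  hp_linear_distance(q)
}

# Hannenhalli-Pevzner distance for a *linear* signed permutation vs identity.
#' @keywords internal
hp_linear_distance <- function(p) {
  n <- length(p)
  if (n == 0L) return(0L)
  # unsigned doubling, framed by 0 and 2n+1; u is 0-based conceptually
  u <- integer(2L * n + 2L)
  u[1L] <- 0L
  for (i in seq_len(n)) {
    v <- p[i]
    if (v > 0L) {
      u[2L * i] <- 2L * v - 1L
      u[2L * i + 1L] <- 2L * v
    } else {
      u[2L * i] <- -2L * v
      u[2L * i + 1L] <- -2L * v - 1L
    }
  }
  u[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L)          # pos[v+1] = 0-based position of value v
  pos[u + 1L] <- 0L:(2L * n + 1L)

  npts <- 2L * n + 2L
  parent <- seq_len(npts)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  # black edges: positions (2k, 2k+1); gray edges: positions of 2k and 2k+1
  glo <- integer(n + 1L); ghi <- integer(n + 1L)
  for (k in 0L:n) {
    unite(2L * k + 1L, 2L * k + 2L)
    i <- pos[2L * k + 1L]; j <- pos[2L * k + 2L]
    unite(i + 1L, j + 1L)
    glo[k + 1L] <- min(i, j)
    ghi[k + 1L] <- max(i, j)
  }
  cyc_of_pt <- vapply(seq_len(npts), find, integer(1))
  c_count <- length(unique(cyc_of_pt))
  b_count <- n + 1L
  # cycle id per gray edge; oriented gray edge: endpoints with equal parity
  gcyc <- cyc_of_pt[glo + 1L]
  gor <- ((ghi - glo) %% 2L) == 0L
  gtriv <- (glo %% 2L == 0L) & (ghi == glo + 1L)   # adjacency

  # interleaving components over cycles
  cyc_ids <- unique(gcyc)
  cparent <- seq_along(cyc_ids)
  cfind <- function(a) {
    while (cparent[a] != a) {
      cparent[a] <<- cparent[cparent[a]]
      a <- cparent[a]
    }
    a
  }
  cidx <- match(gcyc, cyc_ids)
  ne <- n + 1L
  for (e1 in seq_len(ne - 1L)) {
    for (e2 in (e1 + 1L):ne) {
      if ((glo[e1] < glo[e2] && glo[e2] < ghi[e1] && ghi[e1] < ghi[e2]) ||
          (glo[e2] < glo[e1] && glo[e1] < ghi[e2] && ghi[e2] < ghi[e1])) {
        ra <- cfind(cidx[e1]); rb <- cfind(cidx[e2])
        if (ra != rb) cparent[ra] <- rb
      }
    }
  }
  comp_of_edge <- vapply(cidx, cfind, integer(1))
  comps <- unique(comp_of_edge)
  # component summaries
  comp_unoriented <- logical(0)
  comp_pos <- list()
  keep <- logical(0)
  for (cc in comps) {
    e <- which(comp_of_edge == cc)
    nontrivial <- any(!gtriv[e])
    oriented <- any(gor[e] & !gtriv[e])
    comp_unoriented <- c(comp_unoriented, nontrivial && !oriented)
    comp_pos <- c(comp_pos, list(sort(unique(c(glo[e], ghi[e])))))
    keep <- c(keep, nontrivial)
  }
  U <- which(comp_unoriented)
  h <- 0L
  f <- 0L
  if (length(U)) {
    hurdle_set <- function(idx) {
      vapply(idx, function(k) {
        others <- unlist(comp_pos[setdiff(idx, k)])
        if (!length(others)) return(TRUE)
        s <- comp_pos[[k]]
        gap <- findInterval(others, s)
        gap[gap == 0L] <- length(s)
        length(unique(gap)) == 1L
      }, logical(1))
    }
    ish <- hurdle_set(U)
    h <- sum(ish)
    if (h %% 2L == 1L && h >= 1L) {
      hurdles <- U[ish]
      supers <- vapply(hurdles, function(k) {
        rest <- setdiff(U, k)
        if (!length(rest)) return(FALSE)
        newh <- hurdle_set(rest)
        oldh <- U[ish]
        any(newh & !(rest %in% oldh))
      }, logical(1))
      if (length(supers) && all(supers)) f <- 1L
    }
  }
  as.integer(b_count - c_count + h + f)
}

#' Express one block order relative to another
#'
#' Relabels `target` in the frame where `ref` is the identity; sorting the
#' result by inversions transforms `ref` into `target`.
#'
#' @param target,ref `signed_perm` or signed integer vectors over the same
#'   block set
#' @return signed integer vector (circular order)
#' @export
perm_relative <- function(target, ref) {
  t_ <- perm_blocks(target)
  r_ <- perm_blocks(ref)
  if (!setequal(abs(t_), abs(r_))) stop("block sets differ")
  iv <- integer(length(r_))
  iv[abs(r_)] <- seq_along(r_) * sign(r_)
  out <- iv[abs(t_)]
  out[t_ < 0L] <- -out[t_ < 0L]
  as.integer(out)
}

#' Pairwise rearrangement rate
#'
#' Events divided by twice the divergence time (each lineage evolves for
#' `divergence_time_mya` after the split).
#'
#' @param events non-negative integer count of rearrangement events
#' @param divergence_time_mya divergence time in Mya (> 0)
#' @return object of class `rate_estimate`
#' @export
pairwise_rate <- function(events, divergence_time_mya) {
  stopifnot(events >= 0)
  if (divergence_time_mya <= 0) stop("divergence time must be > 0")
  structure(list(events = events, time = divergence_time_mya,
                 mode = "pairwise",
                 rate = events / (2 * divergence_time_mya)),
            class = "rate_estimate")
}

#' Branch rearrangement rate
#'
#' Events divided by the absolute time of the branch.
#'
#' @param events non-negative integer count
#' @param branch_time_mya branch duration in Mya (> 0)
#' @return object of class `rate_estimate`
#' @export
branch_rate <- function(events, branch_time_mya) {
  stopifnot(events >= 0)
  if (branch_time_mya <= 0) stop("branch time must be > 0")
  structure(list(events = events, time = branch_time_mya,
                 mode = "branch", rate = events / branch_time_mya),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate %s> %d event(s) / %.4g Mya = %.4g events/Mya\n",
              x$mode, x$events, x$time, x$rate))
  invisible(x)
}

#' Per-branch rearrangement rates on a dated tree
#'
#' Every node (tips and internal nodes, via `tree$node.label`) must have a
#' block order; per branch, events is the inversion distance between the
#' parent and child orders and rate is events divided by the branch length
#' (Mya).
#'
#' @param tree `ape::phylo`, branch lengths in Mya, internal nodes labelled
#' @param node_orders named list of `signed_perm` / signed integer vectors
#' @return data.frame with parent, child, events, time_mya, rate
#' @export
tree_rates <- function(tree, node_orders) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) {
    stop("tree must carry internal node labels naming the ancestral orders")
  }
  labs <- c(tree$tip.label, tree$node.label)
  missing <- setdiff(labs, names(node_orders))
  if (length(missing)) {
    stop("missing block order for node(s): ", paste(missing, collapse = ", "))
  }
  ne <- nrow(tree$edge)
  out <- data.frame(parent = character(ne), child = character(ne),
                    events = integer(ne), time_mya = numeric(ne),
                    rate = numeric(ne), stringsAsFactors = FALSE)
  for (i in seq_len(ne)) {
    pn <- labs[tree$edge[i, 1L]]
    cn <- labs[tree$edge[i, 2L]]
    ev <- inversion_distance(perm_relative(node_orders[[cn]], node_orders[[pn]]))
    out$parent[i] <- pn
    out$child[i] <- cn
    out$events[i] <- ev
    out$time_mya[i] <- tree$edge.length[i]
    out$rate[i] <- ev / tree$edge.length[i]
  }
  out
}

#' Synteny blocks and a signed permutation from unique shared anchors
#'
#' k-mers occurring exactly once in each genome (counting both strands of
#' B) are used as anchors, chained into maximal collinear, consistently
#' stranded runs, and runs spanning at least `min_block` bp on A become
#' blocks numbered 1..n along A. The order and strand of those blocks along
#' B is returned as a circular signed permutation, together with the
#' fraction of A covered by blocks.
#'
#' @param genomeA,genomeB `circular_sequence` or character strings
#' @param k anchor length (default 21)
#' @param min_block minimum block span on A in bp (default 500)
#' @param max_gap maximum anchor gap within a run (default 1000 bp)
#' @param id_b identifier for the returned permutation
#' @return list with `perm` (`signed_perm` for B relative to A), `n_blocks`,
#'   `blocks` (data.frame of block coordinates on A and B) and `shared`
#'   (shared_bp, genome_bp, percent)
#' @export
blocks_from_anchors <- function(genomeA, genomeB, k = 21L, min_block = 500L,
                                max_gap = 1000L, id_b = "B") {
  dA <- dna_encode(as_seq_string(genomeA))
  dB <- dna_encode(as_seq_string(genomeB))
  LA <- length(dA); LB <- length(dB)
  ca <- kmer_codes(dA, k)
  cbf <- kmer_codes(dB, k)
  cbr <- kmer_codes(dna_revcomp_int(dB), k)

  cnt <- function(v) {
    v <- v[!is.na(v)]
    t <- table(v)
    t
  }
  # occurrence counts keyed by code
  ta <- cnt(ca); tf <- cnt(cbf); tr <- cnt(cbr)
  key_a <- names(ta)[ta == 1L]
  nb <- function(keys, t) {
    out <- as.integer(t[keys]); out[is.na(out)] <- 0L; out
  }
  totB <- nb(key_a, tf) + nb(key_a, tr)
  uniq <- key_a[totB == 1L]
  if (!length(uniq)) stop("no homology detected")
  posA <- match(as.numeric(uniq), ca) - 1L
  pf <- match(as.numeric(uniq), cbf) - 1L
  pr <- match(as.numeric(uniq), cbr) - 1L
  strand <- ifelse(!is.na(pf), "+", "-")
  posB <- ifelse(!is.na(pf), pf, LB - pr - k)  # forward-strand start on B
  o <- order(posA)
  posA <- posA[o]; posB <- posB[o]; strand <- strand[o]

  m <- length(posA)
  if (m == 1L) {
    brk <- logical(0)
  } else {
    dAd <- diff(posA)
    dBd <- diff(posB)
    same <- strand[-1L] == strand[-m]
    okp <- same & strand[-m] == "+" & dBd == dAd
    okm <- same & strand[-m] == "-" & dBd == -dAd
    brk <- !(okp | okm) | dAd > max_gap
  }
  run <- cumsum(c(TRUE, brk))
  first <- which(c(TRUE, brk))
  last <- c(first[-1L] - 1L, m)
  spanA_start <- posA[first]
  spanA_end <- posA[last] + k
  span <- spanA_end - spanA_start
  keep <- span >= min_block
  if (!any(keep)) stop("no homology detected")
  bstartB <- ifelse(strand[first] == "+", posB[first], posB[last])
  bendB <- ifelse(strand[first] == "+", posB[last] + k, posB[first] + k)
  blocks <- data.frame(
    block = seq_len(sum(keep)),
    startA = spanA_start[keep], endA = spanA_end[keep],
    startB = bstartB[keep], endB = bendB[keep],
    strand = strand[first][keep],
    stringsAsFactors = FALSE
  )
  ob <- order(blocks$startB)
  signs <- ifelse(blocks$strand[ob] == "+", 1L, -1L)
  perm <- signed_perm(blocks$block[ob] * signs, genome_id = id_b)
  shared_bp <- sum(blocks$endA - blocks$startA)
  list(
    perm = perm,
    n_blocks = nrow(blocks),
    blocks = blocks,
    shared = list(shared_bp = shared_bp, genome_bp = LA,
                  percent = round(100 * shared_bp / LA, 2))
  )
}
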