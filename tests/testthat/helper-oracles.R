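# Independent oracles used across tests.

# --- exhaustive BFS over circular signed permutations -----------------------
# States are equivalence classes under rotation and reflection; moves are
# arc inversions. Distances from the circular identity are exact shortest
# paths, independent of the breakpoint-graph implementation.

bfs_canon_key <- function(p) {
  n <- length(p)
  best <- NULL
  for (r in list(p, -rev(p))) {
    for (s in seq_len(n)) {
      q <- c(r[s:n], r[seq_len(s - 1L)][seq_len(s - 1L) > 0L])
      k <- paste(q, collapse = ",")
      if (is.null(best) || k < best) best <- k
    }
  }
  best
}

bfs_all_inversions <- function(p) {
  n <- length(p)
  out <- vector("list", n * (n - 1L))
  m <- 0L
  for (s in seq_len(n)) {
    for (l in seq_len(n - 1L)) {
      idx <- ((s - 1L + seq_len(l) - 1L) %% n) + 1L
      q <- p
      q[idx] <- -rev(q[idx])
      m <- m + 1L
      out[[m]] <- q
    }
  }
  out
}

bfs_inversion_distances <- function(n) {
  dist <- new.env(hash = TRUE)
  assign(bfs_canon_key(seq_len(n)), 0L, dist)
  frontier <- list(seq_len(n))
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (q in bfs_all_inversions(p)) {
        k <- bfs_canon_key(q)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d + 1L
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

# --- O(n^2) pairwise-difference nucleotide diversity ------------------------

pi_pairwise_oracle <- function(gt, window_len) {
  per_site <- apply(gt, 1L, function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) return(0)
    diffs <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) diffs <- diffs + (x[i] != x[j])
    }
    diffs / choose(n, 2L)
  })
  sum(per_site) / window_len
}

# --- random circular signed permutation -------------------------------------

random_signed_perm <- function(n) {
  sample(seq_len(n)) * sample(c(-1L, 1L), n, replace = TRUE)
}

# --- raw alignment hit table (BLAST-outfmt6-like input for hit merging) -----

gapless_hits_for_test <- function(query, subject, word = 12L, min_score = 100) {
  dq <- mitostructkit:::dna_encode(query)
  ds <- mitostructkit:::dna_encode(subject)
  h <- mitostructkit:::gapless_hits(dq, ds, word = word)
  h <- h[h$score >= min_score, , drop = FALSE]
  data.frame(start = h$aStart, end = h$aEnd)
}

# --- small simulation fixture shared by recombination tests -----------------

recomb_fixture <- function(seed = 11, f = 0.3, identity = 100,
                           error = 0, genome_length = 6000,
                           rep_len = 400, coverage = 40) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    repeat_spec = data.frame(length = rep_len,
                                             identity = identity, count = 1L),
                    read_length_mean = 1200, read_length_sd = 150,
                    coverage = coverage, recomb_fraction = f,
                    read_error_rate = error)
  g <- gen_circular_genome(cfg)
  list(cfg = cfg, genome = g, pair = g$truth[1L, ])
}
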