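# Synthetic-data generators. Every generator is fully determined by the
# configuration seed (with a fixed per-generator offset so the stages draw
# from distinct but reproducible streams) and returns its ground truth
# alongside the data.

SEED_OFF <- c(genome = 0L, reads = 101L, rearr = 202L, popgen = 303L,
              depth = 404L)

#' Generate a circular genome with planted repeat pairs
#'
#' Background sequence is i.i.d. uniform ACGT, rejection-sampled so that no
#' accidental (non-planted) repeat of 50 bp or more exists in either
#' orientation; planted pairs are separated from each other and from every
#' other planted locus by at least 500 bp of unique sequence, so the truth
#' set is exact.
#'
#' @param cfg `sim_config`; uses seed, genome_length and repeat_spec
#' @return `circular_sequence` whose `truth` field is a `repeat_pairs`
#'   data.frame of the planted pairs
#' @export
gen_circular_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SEED_OFF["genome"])
  L <- cfg$genome_length
  spec <- cfg$repeat_spec
  if (is.null(spec)) spec <- data.frame(length = integer(0), identity = numeric(0),
                                        count = integer(0), orientation = character(0))
  spec <- spec[rep(seq_len(nrow(spec)), spec$count), , drop = FALSE]
  if (nrow(spec)) {
    if (L < 2L * (max(spec$length) + 1000L)) {
      stop("genome too short for the requested repeats")
    }
    if (sum(2L * (spec$length + 1000L)) > L) {
      stop("requested repeats exceed genome length (infeasible packing)")
    }
  }

  sep <- 500L
  for (attempt in 1:50) {
    d <- random_dna_int(L)
    # place repeat pairs without wrapping, buffered by `sep`
    occupied <- matrix(numeric(0), ncol = 2L)
    truth <- list()
    ok <- TRUE
    for (r in seq_len(nrow(spec))) {
      len <- spec$length[r]
      rep_seq <- random_dna_int(len)
      copy2 <- mutate_to_identity(rep_seq, spec$identity[r])
      inverted <- spec$orientation[r] == "inverted"
      placed <- FALSE
      for (try in 1:2000) {
        s1 <- sample.int(L - len - 2L * sep, 1L) + sep
        s2 <- sample.int(L - len - 2L * sep, 1L) + sep
        iv <- rbind(c(s1 - sep, s1 + len + sep), c(s2 - sep, s2 + len + sep))
        if (iv[1L, 2L] > iv[2L, 1L] && iv[2L, 2L] > iv[1L, 1L]) next
        clash <- FALSE
        if (nrow(occupied)) {
          for (q in seq_len(nrow(occupied))) {
            if (any(iv[, 2L] > occupied[q, 1L] & occupied[q, 2L] > iv[, 1L])) {
              clash <- TRUE; break
            }
          }
        }
        if (clash) next
        d[(s1 + 1L):(s1 + len)] <- rep_seq
        d[(s2 + 1L):(s2 + len)] <- if (inverted) dna_revcomp_int(copy2) else copy2
        occupied <- rbind(occupied, iv)
        sA <- min(s1, s2); sB <- max(s1, s2)
        truth[[length(truth) + 1L]] <- data.frame(
          startA = sA, endA = sA + len, strandA = "+",
          startB = sB, endB = sB + len,
          strandB = if (inverted) "-" else "+",
          length = len, identity = spec$identity[r],
          class = classify_repeats(len),
          orientation = spec$orientation[r],
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) stop("could not place requested repeats (infeasible packing)")
    truth <- if (length(truth)) do.call(rbind, truth) else
      empty_repeat_pairs()[, 1:10]
    if (!has_accidental_repeat(d, occupied, k = 25L)) {
      truth <- truth[order(truth$startA, truth$startB), , drop = FALSE]
      rownames(truth) <- NULL
      return(circular_sequence(dna_decode(d), id = "synthetic_mito",
                               truth = truth))
    }
  }
  stop("failed to generate a clean background after 50 attempts")
}

# TRUE if a duplicated k-mer (either orientation) exists with at least one
# copy outside the planted loci. A duplicated 25-mer is a necessary
# condition for any accidental repeat of 50 bp or more.
#' @keywords internal
has_accidental_repeat <- function(d, occupied, k = 25L) {
  co <- kmer_codes(d, k)
  cr <- kmer_codes(dna_revcomp_int(d), k)
  L <- length(d)
  # map rc k-mer index back to forward start
  pos_f <- seq_along(co) - 1L
  pos_r <- L - (seq_along(cr) - 1L) - k
  all_codes <- c(co, cr)
  all_pos <- c(pos_f, pos_r)
  strand <- rep(c(1L, 2L), times = c(length(co), length(cr)))
  dup <- all_codes %in% all_codes[duplicated(all_codes)]
  if (!any(dup)) return(FALSE)
  inside <- rep(FALSE, length(all_pos))
  if (nrow(occupied)) {
    for (q in seq_len(nrow(occupied))) {
      lo <- occupied[q, 1L] + 500L  # occupied includes the 500 bp buffer
      hi <- occupied[q, 2L] - 500L
      inside <- inside | (all_pos >= lo & all_pos + k <= hi)
    }
  }
  bad <- dup & !inside
  # a palindromic k-mer pairs with itself across strands at the same locus
  if (!any(bad)) return(FALSE)
  codes_bad <- unique(all_codes[bad])
  for (cd in codes_bad) {
    idx <- which(all_codes == cd)
    if (length(unique(all_pos[idx])) > 1L) return(TRUE)
  }
  FALSE
}

#' Simulate long reads from a reference/recombinant mixture
#'
#' A fraction `recomb_fraction` of reads is drawn from the two reciprocal
#' crossover conformations of the given repeat pair (flanks exchanged
#' across the repeat, with extended genomic context); the rest are drawn
#' uniformly from the circular reference. Read lengths are lognormal
#' truncated to `[500, 4 * mean]`; substitution errors are i.i.d. at
#' `read_error_rate`; each read is emitted on a random strand.
#'
#' @param genome `circular_sequence` from [gen_circular_genome()]
#' @param pair repeat pair (row of the genome's truth, or compatible list)
#' @param cfg `sim_config`
#' @param n_reads optional read count (default from coverage)
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read, source, start, length, strand)
#' @export
sim_long_reads <- function(genome, pair, cfg, n_reads = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SEED_OFF["reads"])
  d <- dna_encode(as_seq_string(genome))
  L <- length(d)
  p <- pair_fields(pair)
  rep_len <- p$endA - p$startA
  if (cfg$read_length_mean < rep_len + 400) {
    warning("mean read length below repeat length + 400 bp; ",
            "reads cannot span the repeat with both flanks")
  }
  if (is.null(n_reads)) {
    n_reads <- max(1L, round(cfg$coverage * L / cfg$read_length_mean))
  }
  # recombinant conformations are the true crossover products of the pair:
  # a direct-repeat exchange resolves the circle into two subcircles (one
  # carrying the a-b-f junction, the other d-b-c); an inverted-repeat
  # exchange inverts the intervening segment on a single circle. Reads are
  # drawn uniformly over the conformation's total sequence, exactly as for
  # the reference circle.
  if (p$orientation == "direct") {
    l1 <- (p$startB - p$startA) %% L
    conf <- list(recombinant_1 = circ_sub(d, p$startA, l1),
                 recombinant_2 = circ_sub(d, p$startB, L - l1))
  } else {
    seg_len <- (p$endB - p$startA) %% L
    d2 <- d
    idx <- ((p$startA + seq_len(seg_len) - 1L) %% L) + 1L
    d2[idx] <- dna_revcomp_int(d[idx])
    conf <- list(recombinant_inv = d2)
  }
  conf_len <- vapply(conf, length, integer(1))

  mu <- cfg$read_length_mean
  sdl <- sqrt(log(1 + (cfg$read_length_sd / mu)^2))
  ml <- log(mu) - sdl^2 / 2
  lens <- round(stats::rlnorm(n_reads, ml, sdl))
  lens <- pmin(pmax(lens, 500L), 4L * mu)
  lens <- pmin(lens, L)
  is_rec <- stats::runif(n_reads) < cfg$recomb_fraction
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  src <- character(n_reads)
  starts <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    if (is_rec[i]) {
      which_conf <- sample.int(length(conf), 1L, prob = conf_len / sum(conf_len))
      cs <- conf[[which_conf]]
      len <- min(lens[i], length(cs))
      s <- sample.int(length(cs), 1L) - 1L
      rd <- circ_sub(cs, s, len)
      src[i] <- names(conf)[which_conf]
    } else {
      len <- lens[i]
      s <- sample.int(L, 1L) - 1L
      rd <- circ_sub(d, s, len)
      src[i] <- "reference"
    }
    starts[i] <- s
    if (cfg$read_error_rate > 0) {
      err <- which(stats::runif(length(rd)) < cfg$read_error_rate)
      if (length(err)) {
        rd[err] <- (rd[err] + sample.int(3L, length(err), replace = TRUE)) %% 4L
      }
    }
    if (strands[i] == "-") rd <- dna_revcomp_int(rd)
    reads[i] <- dna_decode(rd)
  }
  names(reads) <- sprintf("read%05d", seq_len(n_reads))
  list(reads = reads,
       truth = data.frame(read = names(reads), source = src, start = starts,
                          length = nchar(reads), strand = strands,
                          stringsAsFactors = FALSE))
}

#' Generate an identity/scrambled pair of circular signed permutations
#'
#' The scrambled order is the circular identity transformed by `k` uniform
#' random inversions (random arc: signs flipped, order reversed). The true
#' minimum inversion distance is at most `k`.
#'
#' @param n_blocks number of blocks (>= 3)
#' @param k number of inversions applied
#' @param seed RNG seed
#' @return list with `identity`, `scrambled` (`signed_perm`) and `k`
#' @export
gen_rearranged_pair <- function(n_blocks, k, seed = 1L) {
  stopifnot(n_blocks >= 3L, k >= 0L)
  set.seed(seed + SEED_OFF["rearr"])
  p <- seq_len(n_blocks)
  for (i in seq_len(k)) {
    p <- apply_random_inversion(p)
  }
  list(identity = signed_perm(seq_len(n_blocks), "identity"),
       scrambled = signed_perm(p, "scrambled"),
       k = as.integer(k))
}

#' Apply one uniform random arc inversion to a circular signed permutation
#' @param p signed integer vector
#' @return signed integer vector
#' @export
apply_random_inversion <- function(p) {
  n <- length(p)
  s <- sample.int(n, 1L)
  l <- sample.int(n - 1L, 1L)
  idx <- ((s - 1L + seq_len(l) - 1L) %% n) + 1L
  p[idx] <- -rev(p[idx])
  p
}

#' Generate a two-population haploid variant matrix with planted sweeps
#'
#' Neutral sites share one allele frequency (uniform on `[0.1, 0.9]`)
#' between populations; inside sweep windows the cultivated-population
#' frequency is shifted toward fixation so that expected heterozygosity is
#' divided by the window's `reduction` (an optional `boost` pulls it
#' further). Calls are haploid and phased; missingness is i.i.d.
#'
#' @param cfg `sim_config`; uses seed, genome_length, pop_sizes,
#'   sweep_windows, snp_density, missing_rate
#' @return list with `vm` (`variant_matrix`, populations "wild" and
#'   "cultivated") and `sweep_truth` (the sweep window data.frame)
#' @export
gen_population_variants <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SEED_OFF["popgen"])
  L <- cfg$genome_length
  n1 <- cfg$pop_sizes[1L]; n2 <- cfg$pop_sizes[2L]
  n_sites <- max(2L, round(L * cfg$snp_density))
  pos <- sort(sample.int(L, n_sites))
  p <- stats::runif(n_sites, 0.1, 0.9)
  p_cul <- p
  sw <- cfg$sweep_windows
  if (!is.null(sw) && nrow(sw)) {
    for (w in seq_len(nrow(sw))) {
      inw <- pos >= sw$start[w] & pos <= sw$end[w]
      if (!any(inw)) next
      het <- p[inw] * (1 - p[inw]) / sw$reduction[w]
      disc <- pmax(0, 0.25 - het)
      up <- p[inw] >= 0.5
      q <- ifelse(up, 0.5 + sqrt(disc), 0.5 - sqrt(disc))
      b <- sw$boost[w]
      if (b > 1) q <- ifelse(up, 1 - (1 - q) / b, q / b)
      p_cul[inw] <- q
    }
  }
  gt1 <- vapply(seq_len(n_sites), function(i) {
    stats::rbinom(n1, 1L, p[i])
  }, integer(n1))
  gt2 <- vapply(seq_len(n_sites), function(i) {
    stats::rbinom(n2, 1L, p_cul[i])
  }, integer(n2))
  gt <- cbind(t(gt1), t(gt2))
  colnames(gt) <- c(sprintf("W%03d", seq_len(n1)), sprintf("C%03d", seq_len(n2)))
  if (cfg$missing_rate > 0) {
    gt[stats::runif(length(gt)) < cfg$missing_rate] <- NA_integer_
  }
  pops <- stats::setNames(rep(c("wild", "cultivated"), c(n1, n2)), colnames(gt))
  list(vm = variant_matrix(gt, pos, pops, L),
       sweep_truth = sw)
}

#' Generate per-sample depth summaries from the presence/absence bands
#'
#' Samples carrying the region draw their depth ratio uniformly from the
#' high band, non-carriers from the low band; observed depths get Poisson
#' counting noise (region of `region_len` bp; whole genome of
#' `genome_length` bp at mean depth `coverage`).
#'
#' @param cfg `sim_config`; uses seed, coverage, genome_length, depth_bands
#' @param n_samples number of samples
#' @param presence_truth logical vector (length `n_samples`): region present
#' @param region_len candidate region length in bp (default 5000)
#' @return data.frame sample, Idep, Wdep, ratio, present (truth)
#' @export
gen_depth_profiles <- function(cfg, n_samples, presence_truth,
                               region_len = 5000L) {
  stopifnot(inherits(cfg, "sim_config"),
            length(presence_truth) == n_samples)
  set.seed(cfg$seed + SEED_OFF["depth"])
  b <- cfg$depth_bands
  ratio_true <- ifelse(presence_truth,
                       stats::runif(n_samples, b[3L], b[4L]),
                       stats::runif(n_samples, b[1L], b[2L]))
  L <- cfg$genome_length
  wdep <- stats::rpois(n_samples, cfg$coverage * L) / L
  idep <- stats::rpois(n_samples, ratio_true * cfg$coverage * region_len) / region_len
  data.frame(
    sample = sprintf("S%03d", seq_len(n_samples)),
    Idep = idep, Wdep = wdep,
    ratio = ifelse(wdep > 0, idep / wdep, NA_real_),
    ratio_true = ratio_true,
    present = presence_truth,
    stringsAsFactors = FALSE
  )
}
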