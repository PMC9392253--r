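# Variant filtering, windowed diversity and F_ST, sweep calling.

toy_vm <- function(gt, pos = NULL, ref_len = 1000L,
                   pops = NULL) {
  ns <- ncol(gt)
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("s%02d", seq_len(ns))
  if (is.null(pops)) {
    pops <- stats::setNames(rep(c("wild", "cultivated"), length.out = ns),
                            colnames(gt))
  }
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 10L
  variant_matrix(gt, pos, pops, ref_len)
}

test_that("MAF and missingness filters drop the sites the rules name", {
  n <- 139L
  g_rare <- c(1L, rep(0L, n - 1L))                    # MAF ~ 0.0072
  g_miss <- c(rep(NA_integer_, 21L), rep(c(0L, 1L), length.out = n - 21L))
  g_ok <- rep(c(0L, 1L), length.out = n)
  gt <- rbind(g_rare, g_miss, g_ok)
  vm <- toy_vm(gt, pos = c(10L, 20L, 30L), ref_len = 1000L)
  out <- filter_variants(vm)
  expect_equal(out$pos, 30L)
  # an all-passing matrix is unchanged, order preserved
  gt2 <- rbind(g_ok, rev(g_ok))
  vm2 <- toy_vm(gt2, pos = c(5L, 700L))
  out2 <- filter_variants(vm2)
  expect_identical(out2$gt, vm2$gt)
  expect_identical(out2$pos, vm2$pos)
})

test_that("a half-missing site is removed at the default ceiling", {
  gt <- rbind(c(rep(NA_integer_, 5L), 0L, 1L, 0L, 1L, 0L))
  vm <- toy_vm(gt, pos = 50L)
  expect_equal(nrow(filter_variants(vm)$gt), 0)
})

test_that("windowed pi matches direct pairwise enumeration", {
  # 2 haplotypes, 1 differing site in a 1000-bp window -> 1/1000 per bp
  gt <- rbind(c(0L, 1L))
  vm <- variant_matrix(gt, 100L, c(a = "wild", b = "wild"), 1000L)
  pw <- windowed_pi(vm, "wild", window = 1000L, step = 1000L)
  expect_equal(pw$pi[1L], 1 / 1000)
  # monomorphic window -> 0
  vm0 <- variant_matrix(rbind(c(0L, 0L)), 100L, c(a = "wild", b = "wild"), 1000L)
  expect_equal(windowed_pi(vm0, "wild", 1000L, 1000L)$pi[1L], 0)
  # random toys vs the O(n^2) oracle
  set.seed(42)
  for (rep in 1:5) {
    gt <- matrix(sample(c(0L, 1L, NA_integer_), 30L * 10L, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)), nrow = 30L)
    vm <- toy_vm(gt, pos = sort(sample.int(999L, 30L)), ref_len = 1000L,
                 pops = stats::setNames(rep("wild", 10L), sprintf("s%02d", 1:10)))
    pw <- windowed_pi(vm, "wild", window = 1000L, step = 1000L)
    expect_equal(pw$pi[1L], pi_pairwise_oracle(gt, 1000L), tolerance = 1e-12)
  }
})

test_that("F_ST is 1 for a fixed difference and matches single-site algebra", {
  gt <- rbind(c(rep(0L, 6L), rep(1L, 6L)))
  pops <- stats::setNames(rep(c("wild", "cultivated"), each = 6L),
                          sprintf("s%02d", 1:12))
  vm <- variant_matrix(gt, 100L, pops, 1000L)
  expect_equal(windowed_fst(vm, "wild", "cultivated", 1000L, 1000L)$fst[1L], 1)

  # hand-computed Weir-Cockerham components for one haploid site
  g1 <- c(0L, 0L, 0L, 1L, 1L)   # p1 = 0.4 (allele 1), n1 = 5
  g2 <- c(0L, 1L, 1L, 1L, 1L)   # p2 = 0.8, n2 = 5
  n1 <- 5; n2 <- 5; p1 <- 0.4; p2 <- 0.8
  nbar <- 5; nc <- 10 - 50 / 10; pbar <- 0.6
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  vm2 <- variant_matrix(rbind(c(g1, g2)), 100L,
                        stats::setNames(rep(c("A", "B"), each = 5L),
                                        sprintf("s%02d", 1:10)), 1000L)
  expect_equal(windowed_fst(vm2, "A", "B", 1000L, 1000L)$fst[1L],
               a / (a + b), tolerance = 1e-12)
})

test_that("F_ST of identical populations stays near zero", {
  set.seed(7)
  cfg <- sim_config(seed = 7, genome_length = 20000, pop_sizes = c(25, 25),
                    missing_rate = 0)
  vm <- gen_population_variants(cfg)$vm
  fs <- windowed_fst(vm, "wild", "cultivated", window = 20000L, step = 20000L)
  expect_lt(abs(fs$fst[1L]), 0.05)
})

test_that("the sweep rule needs both thresholds and merges regions", {
  w <- data.frame(start = c(1, 501, 1001, 3001), end = c(1000, 1500, 2000, 4000),
                  fst = c(0.05, 0.3, 0.3, 0.3),
                  ratio = c(5, 3, 3, 1.5))
  out <- call_sweeps(w)
  expect_equal(nrow(out), 1)          # 0.05 fst fails; 1.5 ratio fails
  expect_equal(out$start, 501)
  expect_equal(out$end, 2000)
  expect_equal(out$n_windows, 2)
  # monotone: raising a threshold never adds a region
  expect_lte(nrow(call_sweeps(w, fst_min = 0.35)), nrow(out))
  expect_lte(nrow(call_sweeps(w, ratio_min = 4)), nrow(out))
})

test_that("pi is invariant to sample relabeling and reference rotation", {
  cfg <- sim_config(seed = 19, genome_length = 10000, pop_sizes = c(10, 10),
                    missing_rate = 0)
  vm <- gen_population_variants(cfg)$vm
  pw <- windowed_pi(vm, "wild")
  # relabel samples
  perm <- sample(ncol(vm$gt))
  vm2 <- variant_matrix(vm$gt[, perm], vm$pos, vm$pops[perm], vm$ref_len)
  expect_equal(windowed_pi(vm2, "wild")$pi, pw$pi)
  # rotate the reference by one step: window values shift by one window
  off <- 500L
  pos2 <- ((vm$pos - 1L + off) %% vm$ref_len) + 1L
  o <- order(pos2)
  vm3 <- variant_matrix(vm$gt[o, ], pos2[o], vm$pops, vm$ref_len)
  pw3 <- windowed_pi(vm3, "wild")
  k <- off / 500L
  n <- length(pw$pi)
  expect_equal(pw3$pi[((seq_len(n) - 1L + k) %% n) + 1L], pw$pi,
               tolerance = 1e-12)
})

test_that("variant matrices round-trip through the haploid VCF dialect", {
  cfg <- sim_config(seed = 23, genome_length = 5000, pop_sizes = c(6, 6))
  vm <- gen_population_variants(cfg)$vm
  f <- tempfile(fileext = ".vcf")
  write_vcf_haploid(vm, f)
  back <- read_vcf_haploid(f, vm$pops)
  expect_equal(unname(back$gt), unname(vm$gt))
  expect_equal(back$pos, vm$pos)
  expect_equal(back$ref_len, vm$ref_len)
})
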