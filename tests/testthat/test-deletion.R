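# Depth-ratio genotyping, carrier tables, homology-hit merging, ORF scan.

test_that("depth ratio is the region mean over the genome-wide depth", {
  expect_equal(depth_ratio(30, 15), 2)
  expect_equal(depth_ratio(0, 15), 0)
  expect_equal(depth_ratio(c(10, 20, 30), 20), 1)
  expect_equal(depth_ratio(c(1, 100, 2), 10, method = "median"), 0.2)
  expect_true(is.na(depth_ratio(10, 0)))
})

test_that("presence classification respects bands and is monotone", {
  expect_equal(classify_presence(0.5), "absent")
  expect_equal(classify_presence(20), "present")
  expect_equal(classify_presence(c(0.5, 3, 20), mode = "bands"),
               c("absent", "ambiguous", "present"))
  r <- sort(runif(50, 0, 40))
  calls <- classify_presence(r)
  expect_true(!is.unsorted(match(calls, c("absent", "present"))))
})

test_that("band-generated ratios recover the planted truth completely", {
  cfg <- sim_config(seed = 3)
  truth <- rep(c(TRUE, FALSE), 20)
  dp <- gen_depth_profiles(cfg, length(truth), truth)
  calls <- classify_presence(dp$ratio)
  expect_equal(calls == "present", truth)
  # before noise no ratio falls in the inter-band gap
  expect_false(any(dp$ratio_true > 0.72 & dp$ratio_true < 6.94))
  # determinism: identical TSV on re-run
  f1 <- tempfile(); f2 <- tempfile()
  write_depth_tsv(dp, f1)
  write_depth_tsv(gen_depth_profiles(cfg, length(truth), truth), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("carrier frequencies and chi-square follow the closed form", {
  samples <- sprintf("s%02d", 1:20)
  calls <- stats::setNames(rep(c("present", "absent"), c(10, 10)), samples)
  groups <- stats::setNames(rep(c("G1", "G2"), c(10, 10)), samples)
  ct <- carrier_frequencies(calls, groups)
  expect_equal(ct$chi2, 20)
  expect_equal(ct$pairwise$chi2, 20)
  # equal proportions
  calls2 <- stats::setNames(rep(c("present", "absent"), 10), samples)
  ct2 <- carrier_frequencies(calls2, groups)
  expect_equal(ct2$chi2, 0)
  expect_equal(ct2$p_value, 1)
  # 22 of 33 carriers
  s3 <- sprintf("t%02d", 1:33)
  ct3 <- carrier_frequencies(
    stats::setNames(rep(c("present", "absent"), c(22, 11)), s3),
    stats::setNames(rep("AW", 33), s3))
  expect_equal(ct3$per_group$percent, 66.67)
})

test_that("pairwise chi-square agrees with the standard test on random tables", {
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    samples <- sprintf("s%03d", seq_len(sum(tab)))
    calls <- rep(rep(c("present", "absent"), 2), as.vector(tab))
    groups <- rep(c("A", "A", "B", "B"), as.vector(tab))
    ct <- carrier_frequencies(stats::setNames(calls, samples),
                              stats::setNames(groups, samples))
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ct$pairwise$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ct$pairwise$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("homology hits are length-filtered and unioned order-independently", {
  hits <- data.frame(start = c(0, 50), end = c(100, 150))
  expect_equal(merge_homology_hits(hits)$total_bp, 150)
  expect_equal(merge_homology_hits(hits[2:1, ])$total_bp, 150)
  expect_equal(merge_homology_hits(rbind(hits, hits))$total_bp, 150)
  expect_equal(merge_homology_hits(data.frame(start = 0, end = 99))$total_bp, 0)
  none <- merge_homology_hits(data.frame(start = numeric(0), end = numeric(0)),
                              region_length = 500)
  expect_equal(none$total_bp, 0)
  expect_equal(none$percent, 0)
  m <- merge_homology_hits(data.frame(start = c(0, 300), end = c(200, 500)),
                           region_length = 1000)
  expect_equal(m$total_bp, 400)
  expect_equal(m$percent, 40)
})

test_that("a planted homologous insert is recovered within 1 percent", {
  donor <- gen_circular_genome(sim_config(seed = 51, genome_length = 12000,
                                          repeat_spec = NULL))$seq
  target <- gen_circular_genome(sim_config(seed = 52, genome_length = 12000,
                                           repeat_spec = NULL))$seq
  region <- paste0(substr(target, 1, 3000), substr(donor, 4001, 8000),
                   substr(target, 8001, 11000))
  h <- gapless_hits_for_test(region, donor)
  res <- merge_homology_hits(h, region_length = nchar(region))
  expect_gte(res$total_bp, 4000 * 0.99)
  expect_lte(res$total_bp, 4000 * 1.01)
})

test_that("ORF scan enforces the length floor on both strands", {
  body <- paste(rep(c("GCT", "CAT", "TCT", "GGA"), 12), collapse = "")  # 48 codons
  s150 <- paste0("ATG", body, "TAA")
  expect_equal(nchar(s150), 150)
  o <- orf_scan(s150)
  expect_equal(nrow(o[o$strand == "+", ]), 1)
  expect_equal(o$length[o$strand == "+"], 150)
  # 149-bp open frame: below the floor
  expect_equal(nrow(orf_scan(substr(s150, 1, 149))), 0)
  # reverse-strand ORF reported in forward coordinates
  pad5 <- paste(rep("C", 20), collapse = "")
  pad3 <- paste(rep("C", 30), collapse = "")
  srev <- paste0(pad5, revcomp(s150), pad3)
  orev <- orf_scan(srev)
  hit <- orev[orev$strand == "-" & orev$length == 150, ]
  expect_equal(nrow(hit), 1)
  # srev is 200 bp: 20 bp pad + 150 bp reverse ORF + 30 bp pad, so the ORF
  # occupies forward positions [20, 170)
  expect_equal(hit$start, 20)
  expect_equal(hit$end, 170)
})
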