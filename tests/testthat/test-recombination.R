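# Recombinant reference construction, read assignment, frequency and
# activity summaries.

test_that("identical copies give 2 recombinant forms, diverged copies 6", {
  fx <- recomb_fixture(seed = 11, identity = 100)
  a <- build_recombinant_references(fx$genome, fx$pair)
  expect_true(a$identical_copies)
  expect_equal(sum(a$category == "recombinant"), 2)
  expect_equal(sum(a$category == "reference"), 2)

  fx2 <- recomb_fixture(seed = 12, identity = 95)
  a2 <- build_recombinant_references(fx2$genome, fx2$pair)
  expect_false(a2$identical_copies)
  expect_equal(sum(a2$category == "recombinant"), 6)
  # combinatorial check: {a,d} x {b,e} x {c,f} minus the two references
  expect_equal(2 * 2 * 2 - 2, sum(a2$category == "recombinant"))
  expect_equal(length(unique(a2$forms)), 8)
})

test_that("copies closer than the flank are rejected", {
  g <- gen_circular_genome(sim_config(seed = 2, genome_length = 10000,
                                      repeat_spec = NULL))
  pair <- list(startA = 1000, endA = 1400, startB = 1500, endB = 1900,
               orientation = "direct")
  expect_error(build_recombinant_references(g, pair, flank = 200),
               "closer than the flank")
})

test_that("error-free junction reads are assigned to their arrangement", {
  fx <- recomb_fixture(seed = 11, identity = 100)
  a <- build_recombinant_references(fx$genome, fx$pair)
  # a perfect copy of each form is a fully spanning read
  reads <- c(a$forms["a-b-c"], a$forms["a-b-f"])
  names(reads) <- c("ref_read", "rec_read")
  a2 <- assign_reads(reads, a)
  expect_equal(a2$assignments$category, c("reference", "recombinant"))
  expect_equal(a2$n_ref, 1)
  expect_equal(a2$n_recomb, 1)
  # a read entirely inside the repeat spans no flank: uninformative
  inner <- substr(a$forms["a-b-c"], 260, 500)
  a3 <- assign_reads(c(inner = inner), a)
  expect_equal(a3$assignments$category, "uninformative")
})

test_that("counts partition the read set and survive reverse complementing", {
  fx <- recomb_fixture(seed = 11, f = 0.3)
  a <- build_recombinant_references(fx$genome, fx$pair)
  rs <- sim_long_reads(fx$genome, fx$pair, fx$cfg)
  a2 <- assign_reads(rs$reads, a)
  expect_equal(a2$n_ref + a2$n_recomb + a2$n_uninformative, length(rs$reads))
  rc_reads <- vapply(rs$reads, revcomp, character(1))
  a3 <- assign_reads(rc_reads, a)
  expect_equal(a2$n_ref, a3$n_ref)
  expect_equal(a2$n_recomb, a3$n_recomb)
  expect_equal(a2$n_uninformative, a3$n_uninformative)
})

test_that("assignments never cross truth categories on error-free reads", {
  fx <- recomb_fixture(seed = 11, f = 0.3)
  a <- build_recombinant_references(fx$genome, fx$pair)
  rs <- sim_long_reads(fx$genome, fx$pair, fx$cfg)
  a2 <- assign_reads(rs$reads, a)
  tab <- table(truth = rs$truth$source, call = a2$assignments$category)
  if ("recombinant" %in% colnames(tab)) {
    expect_equal(unname(tab["reference", "recombinant"]), 0)
  }
  if ("reference" %in% colnames(tab)) {
    rec_rows <- grep("^recombinant", rownames(tab), value = TRUE)
    expect_equal(sum(tab[rec_rows, "reference"]), 0)
  }
})

test_that("anchor alignment agrees with an established pairwise aligner", {
  fx <- recomb_fixture(seed = 15, identity = 100, error = 0.005)
  a <- build_recombinant_references(fx$genome, fx$pair)
  rs <- sim_long_reads(fx$genome, fx$pair, fx$cfg)
  a2 <- assign_reads(rs$reads, a)
  inf <- which(a2$assignments$category != "uninformative")[1:5]
  inf <- inf[!is.na(inf)]
  expect_true(length(inf) > 0)
  for (i in inf) {
    form <- a2$assignments$form[i]
    rd <- rs$reads[[i]]
    if (rs$truth$strand[i] == "-") rd <- revcomp(rd)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rd),
                                        Biostrings::DNAString(a$forms[[form]]),
                                        type = "local")
    # the independently computed local identity must also clear the filter
    expect_gt(Biostrings::pid(pa), 99)
  }
})

test_that("recombination frequency follows its definition", {
  mk <- function(nr, nc) list(n_ref = nr, n_recomb = nc)
  expect_equal(recombination_frequency(mk(50, 0)), 0)
  expect_true(is.na(recombination_frequency(mk(0, 0))))
  expect_equal(recombination_frequency(mk(70, 30)), 30)
})

test_that("read filtering keeps mitochondrial and chimeric reads only", {
  m <- gen_circular_genome(sim_config(seed = 31, genome_length = 20000,
                                      repeat_spec = NULL))$seq
  p <- gen_circular_genome(sim_config(seed = 32, genome_length = 15000,
                                      repeat_spec = NULL))$seq
  reads <- c(mito = substr(m, 3001, 4500),
             plastid = substr(p, 3001, 4500),
             chimera = paste0(substr(m, 5001, 5750), substr(p, 8001, 8750)))
  kept <- build_mito_read_set(reads, m, p)
  expect_setequal(names(kept), c("mito", "chimera"))
  expect_warning(build_mito_read_set(character(0), m, p), "empty")
})

test_that("activity summary computes per-class percentages and bands", {
  tab <- data.frame(
    class = c(rep("<100", 6707), rep(">1000", 38)),
    n_recomb = c(rep(1L, 164), rep(0L, 6707 - 164), rep(1L, 33), rep(0L, 5)),
    frequency = c(rep(0.5, 164), rep(NA, 6707 - 164), rep(30, 33), rep(NA, 5))
  )
  s <- activity_summary(tab)
  pc <- s$per_class
  expect_equal(pc$percent_active[pc$class == "<100"], 2.45)
  expect_equal(pc$percent_active[pc$class == ">1000"], 86.84)
  expect_equal(unname(s$bands["below_1"]), 164)
  expect_equal(unname(s$bands["above_20"]), 33)
  none <- activity_summary(data.frame(class = rep("<100", 4), n_recomb = 0L,
                                      frequency = NA_real_))
  expect_equal(none$per_class$percent_active[1], 0)
  expect_equal(none$n_active, 0)
})
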