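# Repeat caller, length classification, plastid-derived segments, genome
# stats.

test_that("length classes use the printed closed integer bins", {
  expect_equal(classify_repeats(c(99, 100, 500, 501, 1000, 1001)),
               c("<100", "100-500", "100-500", "501-1000", "501-1000", ">1000"))
})

test_that("caller has precision and recall 1 on a four-class planted genome", {
  cfg <- sim_config(seed = 42, genome_length = 40000,
                    repeat_spec = data.frame(
                      length = c(60, 300, 800, 2000), identity = 100,
                      count = 1,
                      orientation = c("direct", "direct", "inverted", "direct")))
  g <- gen_circular_genome(cfg)
  found <- find_repeats(g)
  expect_equal(nrow(found), nrow(g$truth))
  key <- function(df) paste(df$startA, df$endA, df$startB, df$endB,
                            df$orientation)
  expect_setequal(key(found), key(g$truth))
  expect_true(all(found$identity == 100))
  inv <- found[found$orientation == "inverted", ]
  expect_equal(inv$strandB, "-")
  expect_equal(inv$length, 800)
})

test_that("repeat calls are invariant to rotating the circular genome", {
  cfg <- sim_config(seed = 9, genome_length = 22000,
                    repeat_spec = data.frame(length = c(300, 1200),
                                             identity = 100, count = 1,
                                             orientation = c("direct", "inverted")))
  g <- gen_circular_genome(cfg)
  base <- find_repeats(g)
  for (off in c(137, 11000, 21000)) {
    rot <- paste0(substr(g$seq, off + 1, g$length), substr(g$seq, 1, off))
    r <- find_repeats(rot)
    expect_equal(nrow(r), nrow(base))
    expect_equal(sort(r$length), sort(base$length))
    expect_equal(sort(r$identity), sort(base$identity))
    expect_equal(sort(r$orientation), sort(base$orientation))
  }
})

test_that("an inverted planted pair matches its direct control", {
  mk <- function(orient) {
    cfg <- sim_config(seed = 5, genome_length = 10000,
                      repeat_spec = data.frame(length = 700, identity = 100,
                                               count = 1, orientation = orient))
    find_repeats(gen_circular_genome(cfg))
  }
  d <- mk("direct"); i <- mk("inverted")
  expect_equal(d$length, i$length)
  expect_equal(d$identity, i$identity)
  expect_equal(i$orientation, "inverted")
})

test_that("repeat summary counts each pair once", {
  cfg <- sim_config(seed = 4, genome_length = 30000,
                    repeat_spec = data.frame(length = c(80, 400, 1500),
                                             identity = 100, count = 1))
  g <- gen_circular_genome(cfg)
  rp <- find_repeats(g)
  sm <- summarize_repeats(rp, g)
  expect_equal(sm$total_count, 3)
  expect_equal(sm$total_length, sum(c(80, 400, 1500)))
  expect_equal(sum(sm$class_counts), sm$total_count)
  expect_equal(sm$genome_size, 30000)
})

test_that("plastid-derived segments are found and unioned", {
  m <- gen_circular_genome(sim_config(seed = 31, genome_length = 20000,
                                      repeat_spec = NULL))$seq
  p <- gen_circular_genome(sim_config(seed = 32, genome_length = 15000,
                                      repeat_spec = NULL))$seq
  mito <- paste0(substr(m, 1, 8000), substr(p, 2001, 7000),
                 substr(m, 13001, 20000))
  res <- identify_plastid_derived(mito, p)
  expect_gte(res$total_bp, 5000)
  expect_equal(nrow(res$intervals), 1)
  expect_equal(res$percent, round(100 * res$total_bp / 20000, 2))
  none <- identify_plastid_derived(m, p)
  expect_equal(none$total_bp, 0)
  expect_equal(none$percent, 0)
})

test_that("genome stats report GC over unambiguous bases to 2 decimals", {
  expect_equal(genome_stats("ACGT")$gc, 50)
  expect_equal(genome_stats("AAAA")$gc, 0)
  expect_equal(genome_stats("GGCC")$gc, 100)
  expect_equal(genome_stats("ACGTN")$gc, 50)   # N excluded from denominator
  expect_equal(genome_stats("ACGTN")$size, 5)
})
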