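# Inversion distance (exact HP), permutation utilities, block finding,
# rates.

test_that("distance is 0 for the circular identity and 1 for one inversion", {
  expect_equal(inversion_distance(1:5), 0)
  expect_equal(inversion_distance(c(1, -2, 3, 4)), 1)
  expect_equal(inversion_distance(c(2, 3, 4, 5, 1)), 0)   # rotation of identity
  expect_equal(inversion_distance(-(5:1)), 0)             # reflection
})

test_that("distance agrees with exhaustive BFS for all n = 4 circular perms", {
  dist <- bfs_inversion_distances(4L)
  keys <- ls(dist)
  for (k in keys) {
    p <- as.integer(strsplit(k, ",")[[1L]])
    expect_identical(inversion_distance(p), dist[[k]])
  }
  expect_gt(length(keys), 30)  # sanity: the state space was enumerated
})

test_that("distance agrees with BFS on sampled n = 5 permutations", {
  dist <- bfs_inversion_distances(5L)
  set.seed(99)
  for (i in 1:200) {
    p <- random_signed_perm(5L)
    expect_identical(inversion_distance(p), dist[[bfs_canon_key(p)]])
  }
})

test_that("distance is invariant under inverse and reflection, and obeys the triangle inequality", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    p <- random_signed_perm(n)
    d <- inversion_distance(p)
    expect_identical(inversion_distance(-rev(p)), d)
    expect_identical(inversion_distance(perm_relative(seq_len(n), p)), d)
    q <- random_signed_perm(n)
    r <- random_signed_perm(n)
    dpr <- inversion_distance(perm_relative(r, p))
    dpq <- inversion_distance(perm_relative(q, p))
    dqr <- inversion_distance(perm_relative(r, q))
    expect_lte(dpr, dpq + dqr)
  }
})

test_that("scrambling by k inversions never exceeds distance k and k<=1 is tight", {
  g0 <- gen_rearranged_pair(7, 0, seed = 1)
  expect_identical(canonicalize_perm(g0$scrambled), canonicalize_perm(g0$identity))
  expect_equal(inversion_distance(perm_relative(g0$scrambled, g0$identity)), 0)
  for (s in 1:10) {
    g1 <- gen_rearranged_pair(7, 1, seed = s)
    expect_equal(inversion_distance(perm_relative(g1$scrambled, g1$identity)), 1)
  }
  dist5 <- bfs_inversion_distances(5L)
  for (s in 1:30) {
    for (k in 2:4) {
      gk <- gen_rearranged_pair(5, k, seed = s * 100 + k)
      rel <- perm_relative(gk$scrambled, gk$identity)
      d <- inversion_distance(rel)
      expect_lte(d, k)
      expect_identical(d, dist5[[bfs_canon_key(rel)]])  # still the true minimum
    }
  }
})

test_that("malformed permutations are rejected", {
  expect_error(signed_perm(c(1, 1, 2)), "permutation")
  expect_error(signed_perm(c(0, 1, 2)), "permutation")
  expect_error(inversion_distance(c(2, 3, 4)), "block 1")
})

test_that("pairwise and branch rates implement their formulas", {
  expect_equal(pairwise_rate(0, 5)$rate, 0)
  expect_equal(pairwise_rate(4, 1.0)$rate, 2.0)
  expect_equal(pairwise_rate(6, 0.6)$rate, 5.0)
  expect_equal(branch_rate(6, 0.05)$rate, 120)
  expect_equal(branch_rate(9, 1.73)$rate, 9 / 1.73)
  expect_error(pairwise_rate(3, 0), "> 0")
  expect_error(branch_rate(3, -1), "> 0")
})

test_that("tree rates divide per-branch events by branch lengths", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5)N1:1.0,C:1.5)R;")
  orders <- list(R = 1:5, N1 = 1:5, A = c(1, -2, 3, 4, 5), B = 1:5, C = 1:5)
  tt <- tree_rates(tr, orders)
  expect_equal(nrow(tt), 4)
  a_row <- tt[tt$child == "A", ]
  expect_equal(a_row$events, 1)
  expect_equal(a_row$rate, 2.0)
  expect_true(all(tt$rate[tt$child != "A"] == 0))
  expect_error(tree_rates(tr, orders[-1]), "R")
})

test_that("blocks from anchors recover identity, inversion and rotation", {
  g <- gen_circular_genome(sim_config(seed = 21, genome_length = 24000,
                                      repeat_spec = NULL))
  s <- g$seq
  same <- blocks_from_anchors(s, s)
  expect_equal(perm_blocks(same$perm), 1L)
  expect_gt(same$shared$percent, 99.5)
  inv <- paste0(substr(s, 1, 8000), revcomp(substr(s, 8001, 16000)),
                substr(s, 16001, 24000))
  bi <- blocks_from_anchors(s, inv)
  expect_equal(bi$n_blocks, 3)
  expect_equal(inversion_distance(bi$perm), 1)
  rot <- paste0(substr(s, 12001, 24000), substr(s, 1, 12000))
  br <- blocks_from_anchors(s, rot)
  expect_equal(inversion_distance(br$perm), 0)
  other <- gen_circular_genome(sim_config(seed = 22, genome_length = 24000,
                                          repeat_spec = NULL))
  expect_error(blocks_from_anchors(s, other$seq, min_block = 500),
               "no homology")
})

test_that("block orders round-trip through TSV", {
  orders <- list(a = signed_perm(c(1, -3, 2), "a"), b = signed_perm(1:3, "b"))
  f <- tempfile(fileext = ".tsv")
  write_block_orders(orders, f)
  back <- read_block_orders(f)
  expect_equal(perm_blocks(back$a), c(1L, -3L, 2L))
  expect_equal(perm_blocks(back$b), 1:3)
})
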