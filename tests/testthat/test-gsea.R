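test_that("ranking metric equals the pooled t and obeys symmetry", {
  m <- toy_matrix(c(1, 2, 3, 3, 4, 5, 0, 0, 0, 0, 0, 0),
                  c("g1", "g2"), paste0("s", 1:6))
  groups <- c(rep("nulliparous", 3), rep("parous", 3))
  rk <- rank_genes(m, groups)
  expect_equal(rk$metric[rk$gene == "g1"], 2 / sqrt(2 / 3), tolerance = 1e-12)

  # identical groups: all metrics zero, order = symbol order
  m0 <- toy_matrix(rep(1:3, 4), c("b", "a"), paste0("s", 1:6))
  m0["a", ] <- m0["b", ]
  rk0 <- rank_genes(m0 + cbind(diag(2) %*% matrix(0, 2, 6)), groups)
  expect_true(all(rk0$metric == 0))
  expect_identical(rk0$gene, c("a", "b"))

  # negating parous values negates metrics and reverses the order
  set.seed(1)
  mr <- matrix(rnorm(12 * 6), 12, 6,
               dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:6)))
  fwd <- rank_genes(mr, groups)
  neg <- mr; neg[, 4:6] <- 2 * matrix(rowMeans(mr[, 1:3]), 12, 3) - neg[, 4:6]
  # reflecting parous values about the nulliparous mean flips every diff
  rev_rk <- rank_genes(neg, groups)
  expect_equal(sort(rev_rk$metric), sort(-fwd$metric), tolerance = 1e-9)
})

test_that("running ES matches the hand-walked worked example", {
  rk <- ranked_fixture(c("a", "b", "c", "d"), c(3, 1, -1, -3))
  r <- running_es(rk, c("a", "d"), p = 1)
  expect_equal(r$running, c(0.5, 0, -0.5, 0), tolerance = 1e-12)
  expect_equal(r$es, 0.5)          # +0.5 beats -0.5 by the tie rule
  expect_equal(r$peak_index, 1L)
  expect_equal(r$hit_positions, c(1L, 4L))
  expect_identical(leading_edge(rk, r), "a")
})

test_that("single-gene sets reach the +/-1 extremes", {
  rk <- ranked_fixture(sprintf("g%d", 1:5), c(4, 2, 1, -1, -2))
  first <- running_es(rk, "g1")
  expect_equal(first$es, 1)
  expect_identical(leading_edge(rk, first), "g1")
  last <- running_es(rk, "g5")
  expect_equal(last$es, -1)
  expect_identical(leading_edge(rk, last), "g5")
})

test_that("degenerate gene sets are rejected", {
  rk <- ranked_fixture(c("a", "b", "c"), c(2, 0, -1))
  expect_error(running_es(rk, c("x", "y")), "no genes")
  expect_error(running_es(rk, c("a", "b", "c")), "whole ranked list")
})

test_that("the walk ends at zero and |ES| <= 1 on random instances", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    rk <- ranked_fixture(sprintf("g%03d", 1:n),
                         sort(rnorm(n), decreasing = TRUE))
    genes <- sample(rk$gene, sample(seq_len(n - 1), 1))
    r <- running_es(rk, genes, p = sample(c(0, 0.5, 1, 2), 1))
    expect_lt(abs(r$running[n]), 1e-9)
    expect_lte(abs(r$es), 1 + 1e-12)
  }
})

test_that("p = 0 is invariant to monotone rescaling of metric magnitudes", {
  set.seed(8)
  rk <- ranked_fixture(sprintf("g%02d", 1:30),
                       sort(rnorm(30), decreasing = TRUE))
  genes <- sample(rk$gene, 7)
  es0 <- running_es(rk, genes, p = 0)$es
  rk_scaled <- ranked_fixture(rk$gene, rk$metric * 7)
  rk_cubed <- ranked_fixture(rk$gene, sign(rk$metric) * abs(rk$metric)^3)
  expect_equal(running_es(rk_scaled, genes, p = 0)$es, es0, tolerance = 1e-12)
  expect_equal(running_es(rk_cubed, genes, p = 0)$es, es0, tolerance = 1e-12)
  # but p = 1 does depend on magnitudes
  expect_false(isTRUE(all.equal(running_es(rk_cubed, genes, p = 1)$es, es0)))
})

test_that("permutation FWER is reproducible and detects planted signal", {
  cfg <- test_cfg(seed = 19L)
  tr <- simulate_training_cohort(cfg)
  r1 <- permutation_fwer(tr$expression, tr$annotation$parity,
                         tr$signature$gene, n_perm = 99, seed = 5)
  r2 <- permutation_fwer(tr$expression, tr$annotation$parity,
                         tr$signature$gene, n_perm = 99, seed = 5)
  expect_identical(r1$es, r2$es)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$fwer, r2$fwer)
  # observed |NES| exceeds every permuted value -> FWER = 0
  expect_equal(r1$fwer, 0)
  expect_true(r1$significant)
  expect_true(all(r1$leading_edge %in% tr$signature$gene))
})

test_that("few distinct relabelings triggers complete enumeration", {
  set.seed(2)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  groups <- rep(c("parous", "nulliparous"), each = 3)
  expect_message(
    r <- permutation_fwer(m, groups, rownames(m)[1:4], n_perm = 500, seed = 1),
    "enumerating all")
  expect_equal(r$n_permutations, choose(6, 3))
})

test_that("refine_signature intersects in first-list order", {
  refined <- refine_signature(list(c("A", "B", "C"), c("B", "C", "D"),
                                   c("C", "B")))
  expect_identical(refined$gene, c("B", "C"))
  ident <- refine_signature(list(c("X", "Y"), c("X", "Y")))
  expect_identical(ident$gene, c("X", "Y"))
  expect_warning(empty <- refine_signature(list("A", "B")), "no genes")
  expect_equal(nrow(empty), 0L)
})
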