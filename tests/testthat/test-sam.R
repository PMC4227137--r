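test_that("d statistic matches the pooled-SE hand computation", {
  m <- toy_matrix(c(1, 2, 3, 3, 4, 5), "g1",
                  paste0("s", 1:6))
  groups <- c(rep("nulliparous", 3), rep("parous", 3))
  m <- rbind(m, g2 = c(2, 2, 2, 2, 2, 2))
  d <- sam_statistic(m, groups, s0 = 0)
  expect_equal(unname(d["g1"]), 2 / sqrt(2 / 3), tolerance = 1e-12)  # 2.449
  expect_true(is.nan(d["g2"]) || d["g2"] == 0)  # zero numerator, zero SE

  # identical groups -> d = 0 for any s0 > 0
  m0 <- toy_matrix(rep(c(1, 2, 3), 2), "g1", paste0("s", 1:6))
  m0 <- rbind(m0, g2 = rep(4:6, 2))
  expect_equal(unname(sam_statistic(m0, groups, s0 = 0.3)), c(0, 0))

  # swapping labels negates d
  swapped <- c(rep("parous", 3), rep("nulliparous", 3))
  expect_equal(sam_statistic(m, swapped, s0 = 0.1),
               -sam_statistic(m, groups, s0 = 0.1))
})

test_that("group size preconditions are enforced", {
  m <- toy_matrix(rnorm(8), c("a", "b"), paste0("s", 1:4))
  expect_error(sam_statistic(m, c("parous", rep("nulliparous", 3))), "at least 2")
  expect_error(sam_statistic(m, c("parous", "parous", "teen", "nulliparous")),
               "parity labels")
})

test_that("s0 selection: fixed passthrough, flat-objective tie rule, grid oracle", {
  set.seed(42)
  groups <- rep(c("parous", "nulliparous"), each = 10)

  # fixed mode bypasses the search
  p <- sam_params(n_permutations = 10, target_fdr = 0.1,
                  s0_mode = "fixed", s0_value = 0.1)
  expect_equal(p$s0_value, 0.1)

  # all genes share the same s -> flat objective -> smallest candidate,
  # which equals that common s at every percentile
  m_flat <- matrix(rep(c(-1, 1), length.out = 20), 60, 20, byrow = TRUE,
                   dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:20)))
  s_common <- unique(round(apply(m_flat, 1, function(x) {
    sqrt((1 / 10 + 1 / 10) * (sum((x[1:10] - mean(x[1:10]))^2) +
                                sum((x[11:20] - mean(x[11:20]))^2)) / 18)
  }), 10))
  expect_length(s_common, 1L)
  expect_equal(as.numeric(choose_s0(m_flat, groups)), s_common, tolerance = 1e-9)

  # heteroskedastic data: choice reproduced by an exhaustive grid search
  # over the same percentile candidates (independent oracle); enough genes
  # that every s-quantile bin holds several of them
  m_het <- matrix(rnorm(400 * 20, sd = rep(seq(0.1, 2, length.out = 400), 20)),
                  400, 20, dimnames = list(sprintf("g%03d", 1:400),
                                           sprintf("s%02d", 1:20)))
  chosen <- choose_s0(m_het, groups)
  s <- apply(m_het, 1, function(x) {
    sqrt((1 / 10 + 1 / 10) * (sum((x[1:10] - mean(x[1:10]))^2) +
                                sum((x[11:20] - mean(x[11:20]))^2)) / 18)
  })
  diffs <- rowMeans(m_het[, 1:10]) - rowMeans(m_het[, 11:20])
  cands <- as.numeric(quantile(s, seq(0, 1, 0.05), names = FALSE))
  breaks <- unique(quantile(s, seq(0, 1, length.out = 101), names = FALSE))
  bin <- cut(s, breaks, include.lowest = TRUE)
  objective <- sapply(cands, function(s0) {
    mads <- tapply(diffs / (s + s0), bin, mad)
    mads <- mads[!is.na(mads)]
    sd(mads) / mean(mads)
  })
  expect_equal(as.numeric(chosen), cands[which.min(objective)], tolerance = 1e-12)
})

test_that("sam_fdr selects nothing on an all-identical matrix", {
  m <- toy_matrix(rep(3, 200 * 12), sprintf("g%03d", 1:200),
                  sprintf("s%02d", 1:12))
  groups <- rep(c("parous", "nulliparous"), each = 6)
  res <- suppressWarnings(
    sam_fdr(m, groups, sam_params(n_permutations = 50, target_fdr = 0.05,
                                  s0_mode = "fixed", s0_value = 0.1, seed = 2)))
  expect_equal(res$n_selected, 0L)
  expect_true(is.na(res$achieved_fdr))
})

test_that("sam_fdr recovers a planted block and yields valid q-values", {
  cfg <- test_cfg(seed = 31L)
  tr <- simulate_training_cohort(cfg)
  res <- sam_fdr(tr$expression, tr$annotation$parity,
                 sam_params(n_permutations = 200, target_fdr = 0.05, seed = 4))
  sel <- res$table$gene[res$table$selected]
  expect_gt(length(sel), 0)
  expect_gt(mean(sel %in% tr$signature$gene), 0.8)  # mostly planted genes
  expect_true(all(res$table$q_value >= 0 & res$table$q_value <= 1))
  expect_true(all(res$table$p_value >= 0 & res$table$p_value <= 1))
  # q monotone non-increasing in d among upregulated genes
  up <- res$table[res$table$d > 0, ]
  up <- up[order(-up$d), ]
  expect_true(all(diff(up$q_value) >= -1e-12))
  # selected genes all positive-d here and fold changes transfer unchanged
  sig <- extract_signature(res, name = "sel")
  expect_true(all(sig$direction == "up"))
  expect_equal(sig$fold_change,
               res$table$fold_change[match(sig$gene, res$table$gene)])
})

test_that("selection at a looser FDR target is a superset", {
  cfg <- test_cfg(seed = 13L, log2fc_range = c(0.1, 0.5))
  tr <- simulate_training_cohort(cfg)
  base <- sam_params(n_permutations = 150, target_fdr = 0.01, seed = 8)
  strict <- sam_fdr(tr$expression, tr$annotation$parity, base)
  loose <- sam_fdr(tr$expression, tr$annotation$parity,
                   sam_params(n_permutations = 150, target_fdr = 0.2, seed = 8))
  sel_strict <- strict$table$gene[strict$table$selected]
  sel_loose <- loose$table$gene[loose$table$selected]
  expect_true(all(sel_strict %in% sel_loose))
})

test_that("d responds to group-specific shifts but not global gene shifts", {
  set.seed(99)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  groups <- rep(c("parous", "nulliparous"), each = 6)
  d0 <- sam_statistic(m, groups, s0 = 0.2)
  m_global <- m; m_global["g01", ] <- m_global["g01", ] + 5
  expect_equal(sam_statistic(m_global, groups, s0 = 0.2)["g01"], d0["g01"])
  m_onegroup <- m; m_onegroup["g01", 1:6] <- m_onegroup["g01", 1:6] + 5
  expect_gt(sam_statistic(m_onegroup, groups, s0 = 0.2)["g01"], d0["g01"])
})

test_that("empty selection yields an empty signature with a warning", {
  m <- toy_matrix(rep(1, 100 * 8), sprintf("g%03d", 1:100), sprintf("s%d", 1:8))
  groups <- rep(c("parous", "nulliparous"), each = 4)
  res <- suppressWarnings(
    sam_fdr(m, groups, sam_params(n_permutations = 20, target_fdr = 0.05,
                                  s0_mode = "fixed", s0_value = 1, seed = 1)))
  expect_warning(sig <- extract_signature(res), "empty")
  expect_equal(nrow(sig), 0L)
})
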