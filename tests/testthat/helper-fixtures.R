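# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-implementations, independent of the package code
# they check.

toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

write_tsv_lines <- function(lines) {
  path <- withr_local_tempfile()
  writeLines(lines, path)
  path
}

# minimal local tempfile helper (deleted by the test runner's tempdir)
withr_local_tempfile <- function() tempfile(fileext = ".tsv")

ranked_fixture <- function(genes, metrics) {
  structure(data.frame(gene = genes, metric = metrics,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Textbook Pearson correlation, written independently of stats::cor.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive two-sided Fisher exact p for a 2x2 table: enumerate all
# tables with the observed margins and sum hypergeometric probabilities
# not exceeding the observed table's (with the conventional 1e-7 relative
# slack for floating-point ties).
fisher_oracle <- function(t) {
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Naive O(n^3) average-linkage agglomeration: returns sorted merge heights.
average_linkage_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_between <- function(g1, g2) mean(d[g1, g2])
  while (length(active) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      dd <- dist_between(active[[i]], active[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  sort(heights)
}

# small synthetic config used across tests (fast, same structure as the
# full-size default)
test_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400L, n_signature_genes = 40L,
         train_n_parous = 20L, train_n_nulliparous = 16L,
         test_n_subjects = 40L, seed = 11L),
    list(...))
  do.call(synthetic_config, args)
}
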