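# Gene set enrichment by a weighted running-sum statistic over a ranked
# gene list, with a phenotype-permutation family-wise error rate.
#
# Genes are ranked by the pooled-variance two-sample t statistic of the
# parous - nulliparous comparison (the regression coefficient divided by
# its standard error). Walking down the ranked list, the running sum rises
# by a signature gene's weighted metric magnitude and falls by a constant
# for every non-signature gene; the enrichment score (ES) is the maximum
# deviation of the walk from zero, bounded in [-1, 1]. Label permutations
# re-rank the list and rebuild the walk; the normalized ES (NES) divides by
# the mean magnitude of same-sign permutation scores, and the FWER is the
# fraction of permutations at least as extreme as observed.

# Pooled-variance two-sample t metric, handling zero-SE genes with a
# capped sentinel so they rank at the extremes rather than crash.
t_metric <- function(diff, s, quiet = FALSE) {
  t <- diff / s
  bad <- !is.finite(t)
  if (any(bad)) {
    cap <- if (any(!bad)) max(abs(t[!bad])) + 1 else 1
    t[bad] <- sign(diff[bad]) * cap
    t[bad & diff == 0] <- 0
    if (!quiet) message(sum(bad), " gene(s) with zero pooled SE capped at the extreme rank")
  }
  t
}

#' Rank genes by the parous-vs-nulliparous t statistic
#'
#' @inheritParams sam_statistic
#' @param welch Use Welch (unequal-variance) t instead of pooled.
#' @return A `ranked_list` data frame (`gene`, `metric`) in descending
#'   metric order, ties broken by gene symbol.
#' @export
rank_genes <- function(m, groups, welch = FALSE) {
  stopifnot_matrix(m)
  stopifnot(length(groups) == ncol(m))
  g <- parity_groups(groups)
  if (welch) {
    n1 <- length(g$parous); n2 <- length(g$nulliparous)
    m1 <- rowMeans(m[, g$parous, drop = FALSE])
    m2 <- rowMeans(m[, g$nulliparous, drop = FALSE])
    v1 <- (rowSums(m[, g$parous, drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (rowSums(m[, g$nulliparous, drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
    diff <- m1 - m2
    s <- sqrt(v1 / n1 + v2 / n2)
  } else {
    st <- pooled_se(m, g$parous, g$nulliparous)
    diff <- st$diff
    s <- st$s
  }
  metric <- t_metric(diff, s)
  ord <- order(-metric, rownames(m))
  structure(data.frame(gene = rownames(m)[ord], metric = metric[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Weighted running-sum enrichment score
#'
#' At rank i the walk rises by `|metric_i|^p / sum_hits |metric_j|^p` for
#' signature genes and falls by `1 / (N - N_hits)` otherwise; by
#' construction it returns to zero after the full list. The ES is the
#' walk's value of maximal absolute deviation from zero, a tie between +v
#' and -v resolved to +v.
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param genes Character vector of signature gene symbols
#'   (case-insensitive); must intersect the ranked list and be a strict
#'   subset of it.
#' @param p Non-negative weight exponent (default 1: magnitude-weighted;
#'   0 gives the unweighted Kolmogorov-Smirnov-like walk).
#' @return List with `es`, `hit_positions`, `peak_index` and the full
#'   `running` sum.
#' @export
running_es <- function(ranked, genes, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), p >= 0)
  hit <- toupper(ranked$gene) %in% toupper(genes)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("signature has no genes in the ranked list", call. = FALSE)
  if (n_hit == nrow(ranked)) stop("signature covers the whole ranked list; miss decrement undefined", call. = FALSE)
  walk <- running_walk(ranked$metric, hit, p)
  hi <- max(walk); lo <- min(walk)
  es <- if (hi >= -lo) hi else lo   # tie between +v and -v -> +v
  peak <- if (es >= 0) which.max(walk) else which.min(walk)
  list(es = es, hit_positions = which(hit), peak_index = peak, running = walk)
}

running_walk <- function(metric, hit, p) {
  w <- abs(metric)^p
  inc <- numeric(length(metric))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / sum(!hit)
  cumsum(inc)
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive ES, the signature genes ranked at or before the peak of
#' the running sum; for a negative ES, those at or after it. These are the
#' genes that drive the enrichment, and intersecting them across analyses
#' refines a signature to its consistent core.
#'
#' @param ranked The `ranked_list` the ES was computed on.
#' @param es_result Result of [running_es()] (or [permutation_fwer()]).
#' @return Character vector of gene symbols in rank order.
#' @export
leading_edge <- function(ranked, es_result) {
  hits <- es_result$hit_positions
  keep <- if (es_result$es >= 0) hits[hits <= es_result$peak_index]
          else hits[hits >= es_result$peak_index]
  ranked$gene[keep]
}

#' Phenotype-permutation enrichment test with FWER
#'
#' Permutes the parity labels `n_perm` times; each permutation re-ranks
#' the full gene list and recomputes the running-sum ES. The normalized
#' score divides an ES by the mean magnitude of same-sign permutation
#' scores, and the family-wise error rate is the fraction of permutations
#' whose |NES| is at least the observed |NES|. With a single gene set this
#' max-statistic FWER reduces to a permutation p-value on |NES|.
#'
#' @inheritParams rank_genes
#' @param genes Signature gene symbols.
#' @param n_perm Number of label permutations.
#' @param p Weight exponent for [running_es()].
#' @param seed Integer seed.
#' @param fwer_threshold Significance threshold on the FWER (default 0.15).
#' @return An `enrichment_result` list: `es`, `nes`, `fwer`, `significant`,
#'   `n_permutations`, `leading_edge`, `hit_positions`, `peak_index`.
#' @export
permutation_fwer <- function(m, groups, genes, n_perm = 1000L, p = 1,
                             seed = 1L, fwer_threshold = 0.15) {
  stopifnot_matrix(m)
  stopifnot(n_perm >= 1L, fwer_threshold > 0, fwer_threshold < 1)
  g <- parity_groups(groups)
  ranked <- rank_genes(m, groups)
  obs <- running_es(ranked, genes, p = p)

  ind <- permutation_indicators(ncol(m), length(g$parous), n_perm, seed)
  n1 <- length(g$parous); n2 <- length(g$nulliparous)
  Dnum <- perm_d_matrix(m, ind, s0 = 0)  # pooled t for every permutation
  hit_set <- toupper(genes)
  symbols <- rownames(m)
  es_perm <- vapply(seq_len(ncol(ind)), function(j) {
    metric <- t_metric(Dnum[, j], 1, quiet = TRUE)  # Dnum already t-scaled
    ord <- order(-metric, symbols)
    hit <- toupper(symbols[ord]) %in% hit_set
    walk <- running_walk(metric[ord], hit, p)
    hi <- max(walk); lo <- min(walk)
    if (hi >= -lo) hi else lo
  }, numeric(1L))

  pos_mean <- mean(abs(es_perm[es_perm >= 0]))
  neg_mean <- mean(abs(es_perm[es_perm < 0]))
  norm_for <- function(es) {
    same <- if (es >= 0) pos_mean else neg_mean
    if (!is.finite(same) || same == 0) same <- mean(abs(es_perm))
    es / same
  }
  nes <- norm_for(obs$es)
  nes_perm <- vapply(es_perm, norm_for, numeric(1L))
  fwer <- mean(abs(nes_perm) >= abs(nes))

  structure(list(es = obs$es, nes = nes, fwer = fwer,
                 significant = fwer <= fwer_threshold,
                 fwer_threshold = fwer_threshold,
                 n_permutations = ncol(ind),
                 leading_edge = leading_edge(ranked, obs),
                 hit_positions = obs$hit_positions,
                 peak_index = obs$peak_index, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES = %.2f, NES = %.2f, FWER = %d%%%s (%d permutations), %d leading-edge gene(s)\n",
              x$es, x$nes, round_half_up(100 * x$fwer, 0),
              if (x$significant) " (sig)" else "", x$n_permutations,
              length(x$leading_edge)))
  invisible(x)
}

#' Intersect leading-edge gene lists into a refined core signature
#'
#' @param core_sets List of two or more character vectors (each nonempty);
#'   the intersection is returned in the order of the first list.
#' @param name Name for the refined signature.
#' @return A [gene_signature()]; empty with a warning when the lists share
#'   no genes.
#' @export
refine_signature <- function(core_sets, name = "core-signature") {
  stopifnot(is.list(core_sets), length(core_sets) >= 2L,
            all(lengths(core_sets) > 0L))
  core <- Reduce(function(a, b) a[toupper(a) %in% toupper(b)], core_sets)
  if (!length(core)) {
    warning("gene lists share no genes; returning an empty signature")
    return(gene_signature(character(0), character(0), numeric(0), name = name))
  }
  gene_signature(core, direction = "up", name = name)
}
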