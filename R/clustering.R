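# Hierarchical clustering of samples over signature genes, and the
# cluster-based parity prediction accuracy.

#' Average-linkage clustering of samples over signature genes
#'
#' Genes are median-centered, sample-sample distances are one minus the
#' Pearson correlation (the Eisen/TreeView convention for expression
#' heatmaps), and agglomeration is average linkage. Samples with zero
#' variance across the clustered genes have undefined correlations and are
#' excluded with a warning. The two-way partition comes from cutting the
#' tree at its root.
#'
#' @param m Expression matrix restricted to the genes of interest
#'   (typically a discovered signature).
#' @return A `cluster_report` list: `tree` (an [stats::hclust] object),
#'   `partition` (named 1/2 vector), `excluded` (sample ids dropped).
#' @export
cluster_samples <- function(m) {
  stopifnot_matrix(m)
  if (ncol(m) < 2L) stop("clustering needs at least 2 samples", call. = FALSE)
  centered <- m - apply(m, 1L, stats::median)
  # correlations are undefined both for flat raw samples and for samples
  # flattened by the median-centering
  sds <- pmin(apply(m, 2L, stats::sd), apply(centered, 2L, stats::sd))
  excluded <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " zero-variance sample(s): ", paste(excluded, collapse = ", "))
    keep <- !(colnames(m) %in% excluded)
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 samples remain after exclusion", call. = FALSE)
    centered <- m - apply(m, 1L, stats::median)
  }
  d <- stats::as.dist(1 - stats::cor(centered))
  tree <- stats::hclust(d, method = "average")
  partition <- stats::cutree(tree, k = 2L)
  structure(list(tree = tree, partition = partition, excluded = excluded),
            class = "cluster_report")
}

#' Parity prediction accuracy from a two-way sample partition
#'
#' The cluster with the higher fraction of parous samples is labelled
#' "predicted parous" (ties go to the larger cluster, then to the
#' lower-numbered one); per-class accuracy is the fraction of each parity
#' class assigned to its predicted cluster.
#'
#' @param report A `cluster_report` from [cluster_samples()], or a named
#'   two-level partition vector.
#' @param annotation Sample annotation with `sample_id` and `parity`.
#' @return Named numeric vector `c(parous_accuracy, nulliparous_accuracy)`.
#' @export
parity_accuracy <- function(report, annotation) {
  partition <- if (inherits(report, "cluster_report")) report$partition else report
  if (length(unique(partition)) < 2L) {
    stop("degenerate single-cluster partition; cannot predict parity", call. = FALSE)
  }
  idx <- match(names(partition), annotation$sample_id)
  if (anyNA(idx)) stop("partition samples missing from annotation", call. = FALSE)
  parity <- annotation$parity[idx]
  frac <- tapply(parity == "parous", partition, mean)
  size <- table(partition)
  ord <- order(-frac, -as.numeric(size), as.numeric(names(frac)))
  parous_cluster <- as.numeric(names(frac))[ord[1L]]
  predicted <- ifelse(partition == parous_cluster, "parous", "nulliparous")
  acc <- function(cls) mean(predicted[parity == cls] == cls)
  c(parous_accuracy = acc("parous"), nulliparous_accuracy = acc("nulliparous"))
}
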