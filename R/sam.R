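# Two-class unpaired SAM-style differential expression with permutation FDR.
#
# The relative-difference statistic is d = (mean_parous - mean_nulliparous)
# / (s + s0), where s is the gene-specific pooled two-sample standard error
# and s0 a small "fudge factor" that stabilises d for low-variance genes.
# Significance thresholds are placed on the deviation of ordered d values
# from their permutation-expected order statistics, and the FDR at a
# threshold is the median number of permutation false calls divided by the
# observed call count.

# Per-gene group means and pooled standard error for one labelling,
# vectorised over genes.
pooled_se <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  ss1 <- rowSums(m[, idx1, drop = FALSE]^2) - n1 * m1^2
  ss2 <- rowSums(m[, idx2, drop = FALSE]^2) - n2 * m2^2
  s <- sqrt((1 / n1 + 1 / n2) * pmax(ss1 + ss2, 0) / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

#' SAM relative-difference statistic
#'
#' `d = (mean_parous - mean_nulliparous) / (s + s0)` per gene, with the
#' nulliparous group as the reference and `s` the pooled two-sample
#' standard error of the mean difference.
#'
#' @param m Expression matrix (genes x samples), complete values.
#' @param groups Parity labels (`"parous"` / `"nulliparous"`) per column.
#' @param s0 Non-negative fudge factor.
#' @return Named numeric vector of d statistics.
#' @export
sam_statistic <- function(m, groups, s0 = 0) {
  stopifnot_matrix(m)
  stopifnot(length(groups) == ncol(m), s0 >= 0)
  g <- parity_groups(groups)
  st <- pooled_se(m, g$parous, g$nulliparous)
  d <- st$diff / (st$s + s0)
  names(d) <- rownames(m)
  d
}

#' Choose the fudge factor s0 by percentile search
#'
#' Candidates are the 0th-100th percentiles (step 5) of the per-gene pooled
#' standard errors `s`. For each candidate the coefficient of variation of
#' `mad(d)` across 100 s-quantile bins is computed; the candidate
#' minimising this dispersion-flatness objective wins, ties going to the
#' smallest candidate.
#'
#' @inheritParams sam_statistic
#' @param probs Percentile grid of candidates.
#' @param nbins Number of s-quantile bins for the objective.
#' @return The chosen s0 (an attribute `cv` carries the objective values).
#' @export
choose_s0 <- function(m, groups, probs = seq(0, 1, by = 0.05), nbins = 100L) {
  stopifnot_matrix(m)
  g <- parity_groups(groups)
  st <- pooled_se(m, g$parous, g$nulliparous)
  if (all(st$s == 0)) {
    warning("all pooled standard errors are zero; s0 = 0")
    return(0)
  }
  candidates <- as.numeric(stats::quantile(st$s, probs, names = FALSE))
  breaks <- unique(stats::quantile(st$s, seq(0, 1, length.out = nbins + 1L),
                                   names = FALSE))
  bin <- if (length(breaks) > 2L) {
    cut(st$s, breaks, include.lowest = TRUE)
  } else {
    factor(rep(1L, length(st$s)))
  }
  cv <- vapply(candidates, function(s0) {
    d <- st$diff / (st$s + s0)
    mads <- tapply(d, bin, stats::mad)
    mads <- mads[!is.na(mads)]
    if (length(mads) < 2L || mean(mads) == 0) return(0)
    stats::sd(mads) / mean(mads)
  }, numeric(1L))
  best <- which(cv <= min(cv) + 1e-12)[1L]  # ties -> smallest candidate
  structure(candidates[best], cv = cv, candidates = candidates)
}

#' Parameters for the SAM permutation-FDR procedure
#'
#' Exactly one of `delta` (a fixed threshold on the deviation from the
#' expected order statistics) or `target_fdr` (the procedure searches the
#' smallest delta whose estimated FDR meets it) must be supplied.
#'
#' @param n_permutations Number of label permutations (complete enumeration
#'   is used when fewer distinct relabelings exist).
#' @param target_fdr Target FDR in (0, 1), or `NULL`.
#' @param delta Fixed non-negative threshold, or `NULL`.
#' @param s0_mode `"percentile_auto"` (search via [choose_s0()]) or
#'   `"fixed"`.
#' @param s0_value Fudge factor when `s0_mode = "fixed"`.
#' @param seed Integer seed for the permutation draw.
#' @param balanced Use balanced permutations (each permuted group drawing
#'   proportionally from both original groups). The default is plain
#'   relabelings: balance cancels chance extremes of the observed
#'   labelling along with true effects, which thins the permutation tail
#'   and makes the threshold search anticonservative.
#' @return A `sam_params` list.
#' @export
sam_params <- function(n_permutations = 1000L, target_fdr = 0.01, delta = NULL,
                       s0_mode = c("percentile_auto", "fixed"), s0_value = NULL,
                       seed = 1L, balanced = FALSE) {
  s0_mode <- match.arg(s0_mode)
  if (is.null(target_fdr) == is.null(delta)) {
    stop("exactly one of target_fdr / delta must be set", call. = FALSE)
  }
  if (!is.null(target_fdr)) stopifnot(target_fdr > 0, target_fdr < 1)
  if (!is.null(delta)) stopifnot(delta >= 0)
  if (s0_mode == "fixed" && is.null(s0_value)) stop("s0_value required when s0_mode = 'fixed'", call. = FALSE)
  stopifnot(n_permutations >= 1L)
  structure(list(n_permutations = as.integer(n_permutations),
                 target_fdr = target_fdr, delta = delta,
                 s0_mode = s0_mode, s0_value = s0_value,
                 seed = as.integer(seed), balanced = isTRUE(balanced)),
            class = "sam_params")
}

# Indicator matrix (samples x B) of permuted parous-group membership.
# Enumerates all C(n, n1) assignments when that is <= B. With
# `balanced = TRUE` (and `idx1` the original group-1 columns) each permuted
# group-1 draws round(n1^2 / n) members from the original group 1 and the
# rest from group 2, so both permuted groups carry (near-)equal fractions
# of any true group effect and the permutation null is not contaminated by
# it -- the balanced scheme of the original SAM procedure.
permutation_indicators <- function(n, n1, B, seed, balanced = FALSE,
                                   idx1 = NULL) {
  n_distinct <- suppressWarnings(choose(n, n1))
  if (is.finite(n_distinct) && n_distinct <= B) {
    combos <- utils::combn(n, n1)
    if (ncol(combos) < B) {
      message("only ", ncol(combos), " distinct relabelings exist; enumerating all")
    }
    ind <- matrix(0, n, ncol(combos))
    ind[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1
    return(ind)
  }
  with_seed(seed, {
    ind <- matrix(0, n, B)
    if (balanced) {
      stopifnot(!is.null(idx1), length(idx1) == n1)
      idx2 <- setdiff(seq_len(n), idx1)
      k1 <- min(max(round(n1^2 / n), n1 - length(idx2)), n1)
      for (b in seq_len(B)) {
        pick <- c(sample(idx1, k1), sample(idx2, n1 - k1))
        ind[pick, b] <- 1
      }
    } else {
      for (b in seq_len(B)) ind[sample.int(n, n1), b] <- 1
    }
    ind
  })
}

# d statistics for all permutations at once via matrix products.
# Returns a genes x B matrix.
perm_d_matrix <- function(m, ind, s0 = 0, statistic = c("sam", "t")) {
  statistic <- match.arg(statistic)
  n <- nrow(ind)
  n1 <- colSums(ind)[1L]
  n2 <- n - n1
  m2 <- m^2
  sum1 <- m %*% ind
  sumsq1 <- m2 %*% ind
  tot <- rowSums(m)
  totsq <- rowSums(m2)
  mean1 <- sum1 / n1
  mean2 <- (tot - sum1) / n2
  ss1 <- sumsq1 - n1 * mean1^2
  ss2 <- (totsq - sumsq1) - n2 * mean2^2
  s <- sqrt((1 / n1 + 1 / n2) * pmax(ss1 + ss2, 0) / (n - 2))
  (mean1 - mean2) / (s + s0)
}

#' SAM permutation-FDR gene selection
#'
#' Orders the observed d statistics, compares them with the
#' permutation-averaged expected order statistics, and for a threshold
#' delta derives upper/lower cut points. Genes beyond a cut are called;
#' FDR(delta) is the expected number of permutation false calls beyond the
#' cuts (mean permutation count, smoothed by one pseudo-count per scanned
#' cut direction so a finite permutation set cannot report an exact zero)
#' divided by the observed call count.
#' When `target_fdr` is given the smallest delta achieving it
#' (with at least one call) is selected. Per-gene q-values are the minimum
#' FDR over thresholds at which the gene is called; per-gene p-values are
#' pooled two-sided permutation tail probabilities.
#'
#' @inheritParams sam_statistic
#' @param params A [sam_params()].
#' @return A `sam_result` list: `table` (gene, d, fold_change, p_value,
#'   q_value, selected), `s0`, `delta`, `achieved_fdr`, `n_selected`,
#'   `n_permutations`, `cuts`.
#' @export
sam_fdr <- function(m, groups, params = sam_params()) {
  stopifnot_matrix(m)
  stopifnot(inherits(params, "sam_params"), length(groups) == ncol(m))
  g <- parity_groups(groups)
  s0 <- if (params$s0_mode == "fixed") params$s0_value else choose_s0(m, groups)
  d <- sam_statistic(m, groups, s0 = s0)
  fc <- 2^(pooled_se(m, g$parous, g$nulliparous)$diff)

  ind <- permutation_indicators(ncol(m), length(g$parous),
                                params$n_permutations, params$seed,
                                balanced = isTRUE(params$balanced),
                                idx1 = g$parous)
  D <- perm_d_matrix(m, ind, s0 = s0)
  B <- ncol(D)
  G <- nrow(D)

  ds <- sort(d)                      # observed order statistics
  Dsort <- apply(D, 2L, sort)        # per-permutation order statistics
  dbar <- rowMeans(Dsort)            # expected order statistics
  dif <- ds - dbar

  # candidate thresholds: a quantile grid over the observed deviations
  # every attainable cut corresponds to some gene's deviation, so the
  # candidate grid is the full set of observed |deviations| (plus 0)
  cand <- sort(unique(c(0, abs(dif))))

  # upper cut: the smallest ds[i] (ds >= 0) with dif[i] >= delta. Running
  # maxima of dif over the non-negative region make this a searchsorted.
  pos <- which(ds >= 0)
  neg <- which(ds <= 0)
  cutup <- rep(Inf, length(cand))
  if (length(pos)) {
    run_max <- cummax(dif[pos])
    first_ge <- findInterval(cand, run_max, left.open = TRUE) + 1L  # first i: run_max >= delta
    hit <- first_ge <= length(pos)
    cutup[hit] <- ds[pos[first_ge[hit]]]
  }
  # lower cut: the largest ds[i] (ds <= 0) with -dif[i] >= delta, via
  # suffix maxima of -dif over the non-positive region
  cutlow <- rep(-Inf, length(cand))
  if (length(neg)) {
    suf_max <- rev(cummax(rev(-dif[neg])))  # non-increasing in i
    n_ge <- length(neg) - findInterval(cand, sort(suf_max), left.open = TRUE)
    hit <- n_ge >= 1L
    cutlow[hit] <- ds[neg[n_ge[hit]]]
  }

  n_called <- (G - findInterval(cutup, ds, left.open = TRUE)) +  # #{d >= cutup}
    findInterval(cutlow, ds)                                     # #{d <= cutlow}

  # per-permutation false-call counts for every candidate at once
  false_counts <- vapply(seq_len(B), function(j) {
    col <- Dsort[, j]
    up <- G - findInterval(cutup, col, left.open = TRUE)   # #{col >= cutup}
    lo <- findInterval(cutlow, col)                        # #{col <= cutlow}
    up + lo
  }, numeric(length(cand)))
  if (is.null(dim(false_counts))) false_counts <- matrix(false_counts, nrow = length(cand))
  # expected false calls: mean permutation count with one pseudo-count per
  # scanned cut direction (a finite-B tail estimate can otherwise hit an
  # exact zero and the two-sided threshold search would overstate
  # confidence at extreme thresholds)
  exp_false <- (rowSums(false_counts) + 2) / (B + 1)
  fdr <- ifelse(n_called > 0, pmin(exp_false / n_called, 1), NA_real_)

  if (!is.null(params$delta)) {
    # the smallest candidate >= the requested delta, else the largest
    k_sel <- if (any(cand >= params$delta)) which(cand >= params$delta)[1L] else length(cand)
  } else {
    ok <- which(n_called > 0 & !is.na(fdr) & fdr <= params$target_fdr)
    k_sel <- if (length(ok)) ok[1L] else NA_integer_
  }

  if (is.na(k_sel) || n_called[k_sel] == 0) {
    selected <- rep(FALSE, G)
    achieved <- NA_real_
    delta_used <- if (!is.null(params$delta)) params$delta else NA_real_
    cuts <- c(lower = -Inf, upper = Inf)
  } else {
    selected <- d >= cutup[k_sel] | d <= cutlow[k_sel]
    achieved <- fdr[k_sel]
    delta_used <- cand[k_sel]
    cuts <- c(lower = cutlow[k_sel], upper = cutup[k_sel])
  }

  # q-values: for each gene the smallest FDR among thresholds calling it.
  # Candidates are ascending in delta so the cuts are nested; a cummin of
  # the FDR sequence gives the best FDR attainable up to each threshold,
  # and the largest threshold still calling a gene is a searchsorted
  # against the monotone cut sequences.
  fdr_filled <- ifelse(is.na(fdr), 1, fdr)
  best_fdr_upto <- cummin(fdr_filled)
  k_up <- findInterval(d, cutup)            # cutup non-decreasing
  k_down <- findInterval(-d, -cutlow)       # -cutlow non-decreasing
  q_up <- ifelse(k_up >= 1L, best_fdr_upto[pmax(k_up, 1L)], 1)
  q_down <- ifelse(k_down >= 1L, best_fdr_upto[pmax(k_down, 1L)], 1)
  q <- pmin(q_up, q_down, 1)
  names(q) <- names(d)

  # pooled two-sided permutation p-values
  absD <- sort(abs(as.vector(D)))
  p <- (length(absD) - findInterval(abs(d), absD, left.open = TRUE) + 1) /
    (length(absD) + 1)

  tab <- data.frame(gene = names(d), d = as.numeric(d),
                    fold_change = as.numeric(fc),
                    p_value = as.numeric(p), q_value = as.numeric(q),
                    selected = selected, stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = as.numeric(s0), delta = delta_used,
                 achieved_fdr = achieved, n_selected = sum(selected),
                 n_permutations = B, cuts = cuts,
                 seed = params$seed),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM result: ", x$n_selected, " gene(s) selected of ", nrow(x$table),
      " (s0 = ", signif(x$s0, 3), ", delta = ", signif(x$delta, 3),
      ", achieved FDR = ", signif(x$achieved_fdr, 3), ", ",
      x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' Turn a SAM selection into a gene signature
#'
#' Selected genes with positive d become `up` entries (and negative d
#' `down`), carrying their linear fold changes, ordered by decreasing |d|.
#'
#' @param r A `sam_result`.
#' @param name Signature name.
#' @return A [gene_signature()]; empty (with a warning) when nothing was
#'   selected.
#' @export
extract_signature <- function(r, name = "parity-signature") {
  stopifnot(inherits(r, "sam_result"))
  tab <- r$table[r$table$selected, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no genes selected; returning an empty signature")
    return(gene_signature(character(0), character(0), numeric(0), name = name))
  }
  tab <- tab[order(-abs(tab$d)), , drop = FALSE]
  gene_signature(tab$gene,
                 direction = ifelse(tab$d > 0, "up", "down"),
                 fold_change = tab$fold_change, name = name)
}

#' Write a SAM result table as TSV
#'
#' @param r A `sam_result`.
#' @param path Output path.
#' @export
write_sam_table <- function(r, path) {
  stopifnot(inherits(r, "sam_result"))
  utils::write.table(r$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
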