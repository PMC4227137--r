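# Orchestration: discover a signature in a training cohort, then test its
# transfer into a paired tumor / adjacent-normal cohort overall and within
# strata (ER status, age at first birth, interval since last birth,
# menopausal status), combining GSEA, Creighton classification and 2x2
# association per analysis cell.

#' Discover a parity signature in a training cohort
#'
#' Runs SAM permutation-FDR selection on the parous-vs-nulliparous
#' comparison, extracts the signature, and (when at least two genes are
#' selected) clusters the samples over the signature genes to measure
#' cluster-based parity prediction accuracy.
#'
#' @param expression Expression matrix (genes x samples), unique gene ids.
#' @param annotation Sample annotation with `sample_id` and `parity`.
#' @param params A [sam_params()].
#' @param signature_name Name for the extracted signature.
#' @param out_dir Optional directory; when given, the signature TSV, the
#'   SAM table and a run summary are written there.
#' @return A `discovery_result` list: `signature`, `sam`, `cluster`,
#'   `accuracy`.
#' @export
run_discovery <- function(expression, annotation, params = sam_params(),
                          signature_name = "parity-signature",
                          out_dir = NULL) {
  stopifnot_matrix(expression)
  ann <- match_annotation(expression, annotation)
  if (!"parity" %in% names(ann)) stop("annotation lacks parity labels", call. = FALSE)
  expression <- impute_missing(expression)
  sam <- sam_fdr(expression, ann$parity, params)
  sig <- suppressWarnings(extract_signature(sam, name = signature_name))
  cluster <- NULL
  accuracy <- c(parous_accuracy = NA_real_, nulliparous_accuracy = NA_real_)
  if (nrow(sig) >= 2L) {
    cluster <- cluster_samples(expression[sig$gene, , drop = FALSE])
    accuracy <- parity_accuracy(cluster, ann)
  }
  res <- structure(list(signature = sig, sam = sam, cluster = cluster,
                        accuracy = accuracy, seed = params$seed),
                   class = "discovery_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature(sig, file.path(out_dir, "signature.tsv"))
    write_sam_table(sam, file.path(out_dir, "sam_table.tsv"))
    summary_lines <- c(
      sprintf("seed\t%d", params$seed),
      sprintf("s0\t%.10g", sam$s0),
      sprintf("n_selected\t%d", sam$n_selected),
      sprintf("achieved_fdr\t%.10g", sam$achieved_fdr),
      sprintf("parous_accuracy\t%.10g", accuracy[["parous_accuracy"]]),
      sprintf("nulliparous_accuracy\t%.10g", accuracy[["nulliparous_accuracy"]]))
    writeLines(summary_lines, file.path(out_dir, "discovery_summary.tsv"))
  }
  res
}

#' @export
print.discovery_result <- function(x, ...) {
  print(x$sam)
  cat(sprintf("cluster-based parity accuracy: parous %.0f%%, nulliparous %.0f%%\n",
              100 * x$accuracy[["parous_accuracy"]],
              100 * x$accuracy[["nulliparous_accuracy"]]))
  invisible(x)
}

# Stratum definitions used by run_transfer. Each returns a logical mask
# over annotation rows (NA-valued covariates drop the sample from that
# stratum only).
stratum_masks <- function(ann, strata) {
  masks <- list(all = rep(TRUE, nrow(ann)))
  if ("er_status" %in% strata) {
    masks[["ER+"]] <- ann$er_status == "positive"
    masks[["ER-"]] <- ann$er_status == "negative"
  }
  if ("age_first_birth" %in% strata) {
    v <- ann$age_first_birth_years
    masks[["AFB<=25"]] <- !is.na(v) & v <= 25 | ann$parity == "nulliparous"
    masks[["AFB>25"]] <- !is.na(v) & v > 25 | ann$parity == "nulliparous"
  }
  if ("years_since_last_birth" %in% strata) {
    v <- ann$years_since_last_birth
    masks[["YSB<10"]] <- !is.na(v) & v < 10 | ann$parity == "nulliparous"
    masks[["YSB>=10"]] <- !is.na(v) & v >= 10 | ann$parity == "nulliparous"
  }
  if ("menopausal" %in% strata) {
    masks[["premenopausal"]] <- ann$menopausal == "pre"
    masks[["postmenopausal"]] <- ann$menopausal == "post"
  }
  masks
}

#' Test a signature's transfer into a cohort, by tissue and stratum
#'
#' For each tissue present in the annotation and each stratum (`all`, then
#' ER+/ER- and any further requested marginal strata), the signature is
#' aligned to the matrix, enriched by [permutation_fwer()], classified by
#' [score_samples()], and the calls are associated with parity by
#' [associate()]. Strata with fewer than `min_per_group` samples in either
#' parity group are skipped with a message rather than an error (tiny
#' ER-negative nulliparous cells are expected in this design).
#'
#' @param expression Expression matrix covering all tissues.
#' @param annotation Annotation with `sample_id`, `parity`, `tissue`,
#'   `er_status` (plus optional stratification covariates).
#' @param signature A [gene_signature()] with fold changes (the Creighton
#'   template falls back to direction mode without them).
#' @param n_perm Permutations per GSEA analysis.
#' @param weight_p Running-sum weight exponent.
#' @param seed Base seed; each analysis cell uses a distinct derived seed.
#' @param fwer_threshold FWER significance threshold (default 0.15).
#' @param strata Extra marginal stratifications beyond `all`: any of
#'   `"er_status"`, `"age_first_birth"`, `"years_since_last_birth"`,
#'   `"menopausal"`.
#' @param min_per_group Minimum samples per parity group in a stratum.
#' @param min_match Signature match-fraction floor for [align_signature()].
#' @return A `transfer_result` list: `table` (one row per analysis cell
#'   with ES/NES/FWER, OR/CI/p and counts) and `details` (the per-cell
#'   enrichment, Creighton and association objects).
#' @export
run_transfer <- function(expression, annotation, signature,
                         n_perm = 1000L, weight_p = 1, seed = 1L,
                         fwer_threshold = 0.15, strata = "er_status",
                         min_per_group = 2L, min_match = 0.5) {
  stopifnot_matrix(expression)
  if (!nrow(signature)) stop("signature is empty", call. = FALSE)
  ann <- match_annotation(expression, annotation)
  expression <- impute_missing(expression)
  aligned <- align_signature(signature, expression, min_match = min_match)
  sig <- aligned$signature
  template_mode <- if (anyNA(sig$fold_change)) "direction" else "median_fc"

  tissues <- intersect(c("normal", "adjacent_normal", "tumor"),
                       unique(ann$tissue))
  rows <- list()
  details <- list()
  counter <- 0L
  for (tissue in tissues) {
    in_tissue <- ann$tissue == tissue
    masks <- stratum_masks(ann, strata)
    for (stratum in names(masks)) {
      counter <- counter + 1L
      keep <- in_tissue & masks[[stratum]]
      sub_ann <- ann[keep, , drop = FALSE]
      n_par <- sum(sub_ann$parity == "parous")
      n_nul <- sum(sub_ann$parity == "nulliparous")
      if (n_par < min_per_group || n_nul < min_per_group) {
        message("skipping ", tissue, " / ", stratum, ": ", n_par,
                " parous, ", n_nul, " nulliparous")
        next
      }
      sub_m <- expression[, keep, drop = FALSE]
      enr <- permutation_fwer(sub_m, sub_ann$parity, sig$gene,
                              n_perm = n_perm, p = weight_p,
                              seed = seed + counter,
                              fwer_threshold = fwer_threshold)
      cls <- score_samples(sub_m, sig, mode = template_mode)
      tab <- contingency_table(calls = cls$call, parity = sub_ann$parity)
      assoc <- associate(tab, haldane = any(tab == 0))
      key <- paste(tissue, stratum, sep = "/")
      details[[key]] <- list(enrichment = enr, creighton = cls,
                             association = assoc)
      rows[[key]] <- data.frame(
        tissue = tissue, stratum = stratum,
        n_parous = n_par, n_nulliparous = n_nul,
        es = enr$es, nes = enr$nes, fwer = enr$fwer,
        significant = enr$significant,
        n_leading_edge = length(enr$leading_edge),
        or_estimate = assoc$or_estimate, ci_low = assoc$ci_low,
        ci_high = assoc$ci_high, p_value = assoc$p_value,
        test_used = assoc$test_used, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no stratum had enough samples in both parity groups", call. = FALSE)
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details, signature = sig,
                 match_fraction = aligned$match_fraction, seed = seed),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Signature transfer (", nrow(x$signature), " genes, ",
      round(100 * x$match_fraction), "% matched)\n", sep = "")
  tab <- x$table
  tab$es <- round_half_up(tab$es)
  tab$nes <- round_half_up(tab$nes)
  tab$fwer <- paste0(round_half_up(100 * tab$fwer, 0), "%",
                     ifelse(tab$significant, " (sig)", ""))
  tab$or <- sprintf("%.2f (%.2f to %.2f)", round_half_up(tab$or_estimate),
                    round_half_up(tab$ci_low), round_half_up(tab$ci_high))
  print(tab[, c("tissue", "stratum", "n_parous", "n_nulliparous",
                "es", "fwer", "or", "p_value", "test_used")],
        row.names = FALSE)
  invisible(x)
}
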