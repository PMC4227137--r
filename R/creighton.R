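# Correlation-template sample classification (the Creighton method): a
# +/-1 standard vector built from the signature's training fold changes is
# correlated against each sample's median-centered expression over the
# signature genes; a positive Pearson correlation calls the sample
# signature-positive.

#' Build the +/-1 template vector of a signature
#'
#' In `"median_fc"` mode (the standard construction) genes with a training
#' fold change above the signature's median fold change get +1 and those
#' below get -1; genes exactly at the median get +1. In `"direction"` mode
#' (the fallback for signatures without fold changes) up-genes get +1 and
#' down-genes -1.
#'
#' @param sig A [gene_signature()].
#' @param mode `"median_fc"` (default) or `"direction"`.
#' @return Named numeric vector of +/-1 over the signature genes.
#' @export
template_vector <- function(sig, mode = c("median_fc", "direction")) {
  mode <- match.arg(mode)
  if (!nrow(sig)) stop("signature is empty", call. = FALSE)
  if (mode == "direction") {
    tpl <- ifelse(sig$direction == "up", 1, -1)
  } else {
    if (anyNA(sig$fold_change)) {
      stop("signature has missing fold changes; use mode = 'direction' instead",
           call. = FALSE)
    }
    med <- stats::median(sig$fold_change)
    tpl <- ifelse(sig$fold_change >= med, 1, -1)  # exact median -> +1
    if (all(tpl == 1) || all(tpl == -1)) {
      warning("degenerate template: all entries have the same sign")
    }
  }
  names(tpl) <- sig$gene
  tpl
}

#' Score samples by correlation with a signature template
#'
#' Each signature gene is median-centered across the dataset's samples;
#' for every sample the Pearson correlation between the template and the
#' centered expression over the matched genes is computed. Samples with
#' r > 0 are called `positive`, all others (including exactly zero and
#' undefined correlations from zero-variance vectors, which are flagged)
#' `negative`.
#'
#' @param m Expression matrix with unique gene rownames.
#' @param sig A [gene_signature()] already aligned to `m` (see
#'   [align_signature()]).
#' @param template Optional precomputed template; default
#'   `template_vector(sig, mode)`.
#' @param mode Template mode, forwarded to [template_vector()].
#' @return A `creighton_result` data frame: `sample_id`, `r`, `call`,
#'   `flagged`.
#' @export
score_samples <- function(m, sig, template = NULL,
                          mode = c("median_fc", "direction")) {
  stopifnot_matrix(m)
  if (is.null(template)) template <- template_vector(sig, mode)
  idx <- match(toupper(names(template)), toupper(rownames(m)))
  ok <- !is.na(idx)
  if (sum(ok) < 3L) {
    stop("fewer than 3 signature genes matched in the matrix; align the signature first",
         call. = FALSE)
  }
  template <- template[ok]
  x <- m[idx[ok], , drop = FALSE]
  centered <- x - apply(x, 1L, stats::median)
  r <- suppressWarnings(as.numeric(stats::cor(template, centered)))
  flagged <- !is.finite(r)
  call <- ifelse(!flagged & r > 0, "positive", "negative")
  if (any(flagged)) {
    warning(sum(flagged), " sample(s) with zero-variance signature expression; ",
            "called negative and flagged")
  }
  structure(data.frame(sample_id = colnames(m), r = r, call = call,
                       flagged = flagged, stringsAsFactors = FALSE),
            class = c("creighton_result", "data.frame"))
}
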