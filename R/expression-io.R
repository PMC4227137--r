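#' Read a tab-delimited expression matrix
#'
#' Reads a genes-in-rows expression table: first row holds sample
#' identifiers, first column gene identifiers, remaining cells log-scale
#' expression values. Duplicate gene rows (multiple probes mapping to one
#' symbol) are retained as-is; use [collapse_probes()] to resolve them.
#' Empty cells and the token `NA` are recorded as missing.
#'
#' @param path Path to a UTF-8 tab-delimited text file.
#' @return A numeric matrix with gene rownames and sample colnames.
#'   Attribute `duplicated_genes` lists symbols occurring more than once.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2L) stop("format error: expression file is empty or has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  # header may or may not carry a label for the gene-id column
  if (length(header) == widths[1L] - 1L) header <- c("gene_id", header)
  if (any(widths != length(header))) {
    stop("format error: ragged rows at line(s) ",
         paste(utils::head(which(widths != length(header)) + 1L, 5L), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicated sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- vapply(body, `[[`, character(1L), 1L)
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  missing_token <- raw == "" | toupper(raw) == "NA"
  values <- suppressWarnings(as.numeric(raw))
  bad <- is.na(values) & !missing_token
  if (any(bad)) {
    stop("format error: non-numeric expression value(s), e.g. '",
         raw[which(bad)[1L]], "'", call. = FALSE)
  }
  m <- matrix(values, nrow = length(genes), ncol = length(sample_ids),
              byrow = TRUE, dimnames = list(genes, sample_ids))
  dups <- unique(genes[duplicated(genes)])
  if (length(dups)) {
    message(length(dups), " gene identifier(s) occur more than once; ",
            "call collapse_probes() before gene-level analyses")
  }
  attr(m, "duplicated_genes") <- dups
  m
}

#' Write an expression matrix as tab-delimited text
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  stopifnot_matrix(m)
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  rows <- paste(rownames(m),
                apply(m, 1L, function(v) paste(format(v, digits = 15, trim = TRUE,
                                                      scientific = FALSE),
                                               collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-delimited, one row per sample, with columns `sample_id`,
#' `subject_id`, `parity` (parous / nulliparous), `tissue` (normal /
#' adjacent_normal / tumor), `er_status` (positive / negative / unknown),
#' `menopausal` (pre / post / unknown) and optional numeric
#' `age_first_birth_years`, `years_since_last_birth`.
#'
#' @param path Path to annotation TSV.
#' @return A data frame validated against the expected levels.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  need <- c("sample_id", "subject_id", "parity", "tissue", "er_status")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$sample_id)) stop("annotation has duplicated sample_id values", call. = FALSE)
  chk <- function(col, levels) {
    bad <- setdiff(unique(ann[[col]]), levels)
    if (length(bad)) stop("annotation column '", col, "' has unknown value(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  chk("parity", c("parous", "nulliparous"))
  chk("tissue", c("normal", "adjacent_normal", "tumor"))
  chk("er_status", c("positive", "negative", "unknown"))
  if ("menopausal" %in% names(ann)) chk("menopausal", c("pre", "post", "unknown"))
  ann
}

#' Collapse duplicate probe rows to one row per gene symbol
#'
#' Microarray platforms map several probes to one gene symbol. `max_mean`
#' keeps, for each symbol, the probe row with the largest mean expression
#' (the most reliably detected probe); `median` takes the element-wise
#' median across a symbol's probe rows. Row order follows the first
#' occurrence of each symbol. Idempotent.
#'
#' @param m Expression matrix, possibly with duplicated rownames.
#' @param rule `"max_mean"` (default) or `"median"`.
#' @return Matrix with unique rownames. Dropped probes are reported via
#'   `message()`.
#' @export
collapse_probes <- function(m, rule = c("max_mean", "median")) {
  rule <- match.arg(rule)
  stopifnot_matrix(m)
  genes <- rownames(m)
  if (!anyDuplicated(genes)) return(m)
  keep_order <- !duplicated(genes)
  out <- m[keep_order, , drop = FALSE]
  dup_syms <- unique(genes[duplicated(genes)])
  for (g in dup_syms) {
    rows <- which(genes == g)
    block <- m[rows, , drop = FALSE]
    out[g, ] <- switch(rule,
      max_mean = block[which.max(rowMeans(block, na.rm = TRUE)), ],
      median = apply(block, 2L, stats::median, na.rm = TRUE)
    )
  }
  message("collapsed ", nrow(m) - nrow(out), " probe row(s) across ",
          length(dup_syms), " duplicated symbol(s) using rule '", rule, "'")
  attr(out, "duplicated_genes") <- character(0)
  out
}

#' Impute missing expression values by per-gene medians
#'
#' Missing cells are replaced by the gene's median across samples, so that
#' downstream statistics see a complete matrix. The number of imputed cells
#' is reported.
#'
#' @param m Expression matrix, possibly containing `NA`.
#' @return Complete matrix.
#' @export
impute_missing <- function(m) {
  stopifnot_matrix(m)
  n_missing <- sum(is.na(m))
  if (n_missing == 0L) return(m)
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("gene(s) with no observed values cannot be imputed: ",
         paste(utils::head(rownames(m)[is.na(med)], 5L), collapse = ", "), call. = FALSE)
  }
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- med[idx[, 1L]]
  message("imputed ", n_missing, " missing value(s) by per-gene medians")
  m
}

#' Construct a gene signature
#'
#' A signature is a data frame of unique gene symbols with a direction
#' (`up` / `down`) and an optional linear-scale training fold change.
#' Direction and fold change must not contradict each other when both are
#' present (`up` with FC < 1 or `down` with FC > 1 is an error).
#'
#' @param gene Character vector of gene symbols.
#' @param direction `"up"` or `"down"` per gene (recycled).
#' @param fold_change Positive linear fold changes or `NA`.
#' @param name Signature name.
#' @return A `gene_signature` data frame with columns `gene`, `direction`,
#'   `fold_change` and a `name` attribute.
#' @export
gene_signature <- function(gene, direction = "up", fold_change = NA_real_,
                           name = "signature") {
  gene <- as.character(gene)
  direction <- rep_len(as.character(direction), length(gene))
  fold_change <- rep_len(as.numeric(fold_change), length(gene))
  if (anyDuplicated(gene)) {
    stop("signature gene symbols must be unique: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "), call. = FALSE)
  }
  bad_dir <- !direction %in% c("up", "down")
  if (any(bad_dir)) {
    stop("format error: unknown direction token(s): ",
         paste(unique(direction[bad_dir]), collapse = ", "), call. = FALSE)
  }
  has_fc <- !is.na(fold_change)
  if (any(has_fc & fold_change <= 0)) stop("fold changes must be positive", call. = FALSE)
  # strict contradiction only; FC exactly 1 carries no direction information
  inconsistent <- has_fc & ((direction == "up" & fold_change < 1) |
                              (direction == "down" & fold_change > 1))
  if (any(inconsistent)) {
    stop("direction inconsistent with fold change for: ",
         paste(gene[inconsistent], collapse = ", "), call. = FALSE)
  }
  sig <- data.frame(gene = gene, direction = direction,
                    fold_change = fold_change, stringsAsFactors = FALSE)
  attr(sig, "name") <- name
  class(sig) <- c("gene_signature", "data.frame")
  sig
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", attr(x, "name"), "': ", nrow(x), " gene(s), ",
      sum(x$direction == "up"), " up / ", sum(x$direction == "down"),
      " down\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Read a gene signature from TSV or GMT
#'
#' TSV format: header `gene`, `direction`, optional `fold_change`. GMT
#' format: one line, `name<TAB>description<TAB>gene1<TAB>gene2...`; all GMT
#' genes are taken as upregulated with no fold change.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"`; default guessed from the extension.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    fields <- strsplit(readLines(path)[1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop("format error: GMT line needs name, description and genes", call. = FALSE)
    return(gene_signature(fields[-(1:2)], direction = "up", name = fields[1L]))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(tab))) {
    stop("format error: signature TSV needs columns 'gene' and 'direction'", call. = FALSE)
  }
  fc <- if ("fold_change" %in% names(tab)) tab$fold_change else NA_real_
  name <- sub("\\.[^.]*$", "", basename(path))
  gene_signature(tab$gene, tab$direction, fc, name = name)
}

#' Write a gene signature to TSV or GMT
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @param format `"tsv"` or `"gmt"`.
#' @export
write_signature <- function(sig, path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    writeLines(paste(c(attr(sig, "name"), "paritysig signature", sig$gene),
                     collapse = "\t"), path)
  } else {
    out <- data.frame(gene = sig$gene, direction = sig$direction,
                      fold_change = format(sig$fold_change, digits = 15, trim = TRUE))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a signature to genes present in a dataset
#'
#' Case-insensitive symbol matching against the matrix rownames, preserving
#' signature order. Errors when the matched fraction falls below
#' `min_match`, naming the missing genes, since a poorly matched signature
#' cannot be meaningfully transferred.
#'
#' @param sig A [gene_signature()].
#' @param m Expression matrix with unique gene rownames.
#' @param min_match Minimum acceptable matched fraction (default 0.5).
#' @return List with `signature` (restricted, gene symbols rewritten to the
#'   dataset's casing) and `match_fraction`.
#' @export
align_signature <- function(sig, m, min_match = 0.5) {
  stopifnot_matrix(m)
  if (anyDuplicated(rownames(m))) stop("matrix gene ids must be unique; collapse probes first", call. = FALSE)
  idx <- match(toupper(sig$gene), toupper(rownames(m)))
  matched <- !is.na(idx)
  frac <- mean(matched)
  if (frac < min_match) {
    stop("only ", round(100 * frac), "% of signature genes found (floor ",
         round(100 * min_match), "%); missing: ",
         paste(utils::head(sig$gene[!matched], 10L), collapse = ", "), call. = FALSE)
  }
  out <- sig[matched, , drop = FALSE]
  out$gene <- rownames(m)[idx[matched]]
  attr(out, "name") <- attr(sig, "name")
  class(out) <- class(sig)
  list(signature = out, match_fraction = frac)
}
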