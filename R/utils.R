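# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Half-up decimal rounding, the convention used for report formatting
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  }
  invisible(m)
}

# Map a parity label vector into indices for the two comparison groups,
# with the nulliparous group as the reference.
parity_groups <- function(groups) {
  groups <- as.character(groups)
  ok <- groups %in% c("parous", "nulliparous")
  if (!all(ok)) {
    stop("parity labels must be 'parous' or 'nulliparous'; found: ",
         paste(unique(groups[!ok]), collapse = ", "), call. = FALSE)
  }
  idx1 <- which(groups == "parous")
  idx2 <- which(groups == "nulliparous")
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("each parity group needs at least 2 samples (parous = ",
         length(idx1), ", nulliparous = ", length(idx2), ")", call. = FALSE)
  }
  list(parous = idx1, nulliparous = idx2)
}

# Align an annotation table to the columns of an expression matrix.
match_annotation <- function(m, annotation) {
  if (!"sample_id" %in% names(annotation)) {
    stop("annotation must contain a 'sample_id' column", call. = FALSE)
  }
  idx <- match(colnames(m), annotation$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from annotation: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  annotation[idx, , drop = FALSE]
}
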