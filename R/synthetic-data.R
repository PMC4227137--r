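#' Configuration for synthetic cohort generation
#'
#' The defaults mirror the study design the package targets: a training
#' cohort of 130 reduction-mammoplasty samples (76 parous, 54 nulliparous)
#' profiled for 10,000 genes with a planted block of 251 parity-upregulated
#' genes, and a paired test cohort of 150 breast-cancer subjects (79%
#' parous, 78% ER-positive) contributing one cancer-adjacent normal and one
#' tumor sample each. Planted log2 effects are drawn uniformly from
#' `log2fc_range` (default 0.2-0.9, i.e. linear fold changes of roughly
#' 1.1-1.9, the scale of the reported training effects). In the test cohort
#' the planted shift is multiplied by a tissue- and ER-dependent
#' attenuation: partially preserved in ER+ adjacent-normal tissue, further
#' diluted in ER+ tumors, and disrupted (default 0) in ER- subjects.
#'
#' @param n_genes Number of genes on the simulated platform.
#' @param n_signature_genes Number of planted parity-upregulated genes.
#' @param train_n_parous,train_n_nulliparous Training group sizes.
#' @param test_n_subjects Number of paired test subjects.
#' @param test_parous_fraction,test_er_positive_fraction Bernoulli rates for
#'   parity and ER status in the test cohort.
#' @param log2fc_range Range (low, high) of planted additive log2 shifts.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param baseline Mean background log2 expression.
#' @param attenuation_adjacent_erpos,attenuation_tumor_erpos,attenuation_erneg
#'   Multipliers in `[0, 1]` applied to the planted shift in the respective
#'   test-tissue / ER stratum.
#' @param block_size,block_cor Optional gene-gene correlation: genes are
#'   grouped into blocks of `block_size` sharing an equicorrelated noise
#'   component with correlation `block_cor` (0 disables, the default).
#' @param seed Integer seed driving every random draw.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 10000L, n_signature_genes = 251L,
                             train_n_parous = 76L, train_n_nulliparous = 54L,
                             test_n_subjects = 150L,
                             test_parous_fraction = 0.79,
                             test_er_positive_fraction = 0.78,
                             log2fc_range = c(0.2, 0.9), noise_sd = 0.5,
                             baseline = 7,
                             attenuation_adjacent_erpos = 0.8,
                             attenuation_tumor_erpos = 0.4,
                             attenuation_erneg = 0,
                             block_size = 0L, block_cor = 0,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              train_n_parous = as.integer(train_n_parous),
              train_n_nulliparous = as.integer(train_n_nulliparous),
              test_n_subjects = as.integer(test_n_subjects),
              test_parous_fraction = test_parous_fraction,
              test_er_positive_fraction = test_er_positive_fraction,
              log2fc_range = as.numeric(log2fc_range), noise_sd = noise_sd,
              baseline = baseline,
              attenuation_adjacent_erpos = attenuation_adjacent_erpos,
              attenuation_tumor_erpos = attenuation_tumor_erpos,
              attenuation_erneg = attenuation_erneg,
              block_size = as.integer(block_size), block_cor = block_cor,
              seed = as.integer(seed))
  stopifnot(cfg$n_signature_genes <= cfg$n_genes,
            cfg$n_genes >= 1L, cfg$train_n_parous >= 1L,
            cfg$train_n_nulliparous >= 1L, cfg$test_n_subjects >= 1L,
            length(cfg$log2fc_range) == 2L,
            all(cfg$log2fc_range >= 0), diff(cfg$log2fc_range) >= 0,
            cfg$noise_sd >= 0,
            cfg$test_parous_fraction >= 0, cfg$test_parous_fraction <= 1,
            cfg$test_er_positive_fraction >= 0, cfg$test_er_positive_fraction <= 1,
            all(c(cfg$attenuation_adjacent_erpos, cfg$attenuation_tumor_erpos,
                  cfg$attenuation_erneg) >= 0))
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

# Gaussian noise matrix, optionally with equicorrelated blocks of genes.
noise_matrix <- function(cfg, n_samples) {
  e <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
              cfg$n_genes, n_samples)
  if (cfg$block_size > 1L && cfg$block_cor > 0) {
    block <- (seq_len(cfg$n_genes) - 1L) %/% cfg$block_size
    z <- matrix(stats::rnorm((max(block) + 1L) * n_samples, 0, cfg$noise_sd),
                max(block) + 1L, n_samples)
    e <- sqrt(1 - cfg$block_cor) * e +
      sqrt(cfg$block_cor) * z[block + 1L, , drop = FALSE]
  }
  e
}

#' Simulate a nulliparous-vs-parous training cohort
#'
#' Background genes are identically distributed in both groups; each of the
#' `n_signature_genes` planted genes receives an additive log2 shift, drawn
#' uniformly from `log2fc_range`, in parous samples only. The ground-truth
#' signature (direction `up`, the drawn linear fold changes) is returned so
#' recovery can be scored.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `expression` (matrix), `annotation` (data frame,
#'   `tissue = "normal"`) and `signature` (ground truth).
#' @export
simulate_training_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    genes <- synthetic_gene_ids(cfg)
    n1 <- cfg$train_n_parous
    n2 <- cfg$train_n_nulliparous
    n <- n1 + n2
    sig_idx <- sort(sample.int(cfg$n_genes, cfg$n_signature_genes))
    lfc <- stats::runif(cfg$n_signature_genes,
                        cfg$log2fc_range[1L], cfg$log2fc_range[2L])
    m <- cfg$baseline + noise_matrix(cfg, n)
    parity <- rep(c("parous", "nulliparous"), c(n1, n2))
    m[sig_idx, parity == "parous"] <- m[sig_idx, parity == "parous"] + lfc
    ids <- sprintf("RM%03d", seq_len(n))
    dimnames(m) <- list(genes, ids)
    menopausal <- sample(c("pre", "post"), n, replace = TRUE, prob = c(0.65, 0.35))
    afb <- ifelse(parity == "parous",
                  pmin(pmax(round(stats::rnorm(n, 24, 4)), 16), 40), NA_real_)
    ysl <- ifelse(parity == "parous", round(stats::runif(n, 0, 15), 1), NA_real_)
    ann <- data.frame(sample_id = ids, subject_id = ids, parity = parity,
                      tissue = "normal", er_status = "unknown",
                      menopausal = menopausal,
                      age_first_birth_years = afb,
                      years_since_last_birth = ysl,
                      stringsAsFactors = FALSE)
    sig <- gene_signature(genes[sig_idx], direction = "up",
                          fold_change = 2^lfc, name = "planted-parity-signature")
    list(expression = m, annotation = ann, signature = sig, seed = cfg$seed)
  })
}

#' Simulate a paired tumor / adjacent-normal test cohort
#'
#' Each subject contributes one cancer-adjacent normal and one tumor sample
#' sharing a `subject_id`. Parity and ER status are Bernoulli with the
#' configured fractions. Parous subjects receive the signature's log2 shift
#' scaled by `attenuation_adjacent_erpos` / `attenuation_tumor_erpos` when
#' ER-positive and by `attenuation_erneg` (both tissues) when ER-negative;
#' nulliparous subjects receive no shift.
#'
#' @param cfg A [synthetic_config()].
#' @param sig A [gene_signature()] with fold changes, typically the ground
#'   truth from [simulate_training_cohort()]; its genes must exist on the
#'   simulated platform.
#' @return List with `expression` and `annotation`.
#' @export
simulate_test_cohort <- function(cfg, sig) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!nrow(sig)) stop("signature must be nonempty", call. = FALSE)
  with_seed(cfg$seed + 1L, {
    genes <- synthetic_gene_ids(cfg)
    sig_idx <- match(toupper(sig$gene), toupper(genes))
    if (anyNA(sig_idx)) {
      stop("signature gene(s) absent from the simulated platform: ",
           paste(utils::head(sig$gene[is.na(sig_idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    lfc <- log2(sig$fold_change)  # signed: down-genes have FC < 1
    if (anyNA(lfc)) stop("signature fold changes required to plant the test-cohort shift", call. = FALSE)
    ns <- cfg$test_n_subjects
    parity <- ifelse(stats::rbinom(ns, 1L, cfg$test_parous_fraction) == 1L,
                     "parous", "nulliparous")
    er <- ifelse(stats::rbinom(ns, 1L, cfg$test_er_positive_fraction) == 1L,
                 "positive", "negative")
    subj <- sprintf("PB%03d", seq_len(ns))
    tissues <- c("adjacent_normal", "tumor")
    n <- 2L * ns
    m <- cfg$baseline + noise_matrix(cfg, n)
    ids <- paste0(rep(subj, each = 2L), c("_N", "_T"))
    dimnames(m) <- list(genes, ids)
    att <- matrix(0, ns, 2L, dimnames = list(NULL, tissues))
    att[er == "positive", "adjacent_normal"] <- cfg$attenuation_adjacent_erpos
    att[er == "positive", "tumor"] <- cfg$attenuation_tumor_erpos
    att[er == "negative", ] <- cfg$attenuation_erneg
    for (k in seq_len(ns)) {
      if (parity[k] == "parous") {
        cols <- 2L * k - 1:0  # adjacent_normal then tumor
        m[sig_idx, cols[1L]] <- m[sig_idx, cols[1L]] + lfc * att[k, 1L]
        m[sig_idx, cols[2L]] <- m[sig_idx, cols[2L]] + lfc * att[k, 2L]
      }
    }
    menopausal <- sample(c("pre", "post"), ns, replace = TRUE, prob = c(0.27, 0.73))
    afb <- ifelse(parity == "parous",
                  pmin(pmax(round(stats::rnorm(ns, 25, 5)), 16), 42), NA_real_)
    ysl <- ifelse(parity == "parous",
                  round(pmax(stats::rnorm(ns, 25, 8), 0), 1), NA_real_)
    ann <- data.frame(sample_id = ids,
                      subject_id = rep(subj, each = 2L),
                      parity = rep(parity, each = 2L),
                      tissue = rep(tissues, ns),
                      er_status = rep(er, each = 2L),
                      menopausal = rep(menopausal, each = 2L),
                      age_first_birth_years = rep(afb, each = 2L),
                      years_since_last_birth = rep(ysl, each = 2L),
                      stringsAsFactors = FALSE)
    list(expression = m, annotation = ann, seed = cfg$seed)
  })
}
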