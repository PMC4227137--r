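# 2x2 association of signature call with parity: cross-product odds ratio,
# Wald confidence interval, and a chi-square or Fisher exact p-value chosen
# by the minimum expected cell count.

#' Build a parity x signature-call 2x2 table
#'
#' Fixed orientation: rows nulliparous / parous, columns negative /
#' positive, so cell `a` counts nulliparous signature-negative subjects and
#' `d` parous signature-positive ones.
#'
#' @param a,b,c,d Non-negative integer counts (nulliparous-negative,
#'   nulliparous-positive, parous-negative, parous-positive); or give
#'   `calls` and `parity` vectors instead.
#' @param calls Character vector of `positive` / `negative` calls.
#' @param parity Matching vector of `parous` / `nulliparous` labels.
#' @return A 2x2 integer matrix with dimnames.
#' @export
contingency_table <- function(a = NULL, b = NULL, c = NULL, d = NULL,
                              calls = NULL, parity = NULL) {
  if (!is.null(calls)) {
    stopifnot(length(calls) == length(parity))
    a <- sum(parity == "nulliparous" & calls == "negative")
    b <- sum(parity == "nulliparous" & calls == "positive")
    c <- sum(parity == "parous" & calls == "negative")
    d <- sum(parity == "parous" & calls == "positive")
  }
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) >= 1)
  matrix(as.integer(counts), 2L, 2L, byrow = TRUE,
         dimnames = list(parity = c("nulliparous", "parous"),
                         call = c("negative", "positive")))
}

table_cells <- function(t) {
  stopifnot(is.matrix(t), all(dim(t) == 2L))
  list(a = t[1L, 1L], b = t[1L, 2L], c = t[2L, 1L], d = t[2L, 2L])
}

haldane_or_stop <- function(t, haldane) {
  if (any(t == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE to add 0.5 to all cells",
           call. = FALSE)
    }
    t <- t + 0.5
  }
  t
}

#' Cross-product odds ratio of a 2x2 table
#'
#' `OR = (d * a) / (c * b)`: the odds of being signature-positive among
#' parous versus nulliparous subjects, identical to the
#' single-binary-covariate logistic-regression MLE.
#'
#' @param t A 2x2 table from [contingency_table()].
#' @param haldane Apply the Haldane-Anscombe +0.5 correction when a cell is
#'   zero (opt-in; otherwise a zero cell is an error).
#' @return The odds-ratio estimate.
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  t <- haldane_or_stop(t, haldane)
  x <- table_cells(t)
  (x$d * x$a) / (x$c * x$b)
}

#' Wald confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
wald_ci <- function(t, level = 0.95, haldane = FALSE) {
  t <- haldane_or_stop(t, haldane)
  x <- table_cells(t)
  se <- sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log((x$d * x$a) / (x$c * x$b))
  c(ci_low = exp(lor - z * se), ci_high = exp(lor + z * se))
}

#' Chi-square or Fisher test for a 2x2 table
#'
#' Uses Pearson's chi-square with 1 df and no continuity correction unless
#' the minimum expected cell count (row total x column total / grand
#' total) is below five, in which case the two-sided Fisher exact test
#' (summing hypergeometric probabilities no larger than the observed
#' table's) is used.
#'
#' @param t A 2x2 table.
#' @return List with `p_value`, `test_used` (`"chi2"` / `"fisher"` /
#'   `"undefined"` for a zero margin) and `min_expected_count`.
#' @export
association_test <- function(t) {
  stopifnot(is.matrix(t), all(dim(t) == 2L), all(t >= 0))
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  min_expected <- min(expected)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    warning("zero margin; association p-value undefined")
    return(list(p_value = NA_real_, test_used = "undefined",
                min_expected_count = min_expected))
  }
  if (min_expected < 5) {
    p <- stats::fisher.test(t)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(t, correct = FALSE)$p.value
    test <- "chi2"
  }
  list(p_value = min(p, 1), test_used = test, min_expected_count = min_expected)
}

#' Full association summary of signature call versus parity
#'
#' Combines the cross-product odds ratio, Wald interval and the
#' chi-square/Fisher p-value; also reports the Wald z p-value on the log
#' odds ratio as a secondary statistic.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level for the Wald interval.
#' @return An `association_result` list: `counts`, `or_estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `p_wald`, `test_used`,
#'   `min_expected_count`.
#' @export
associate <- function(t, level = 0.95, haldane = FALSE) {
  test <- association_test(t)
  tc <- haldane_or_stop(t, haldane)
  x <- table_cells(tc)
  or <- (x$d * x$a) / (x$c * x$b)
  ci <- wald_ci(t, level = level, haldane = haldane)
  se <- sqrt(1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d)
  p_wald <- 2 * stats::pnorm(-abs(log(or)) / se)
  structure(list(counts = t, or_estimate = or,
                 ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
                 p_value = test$p_value, p_wald = p_wald,
                 test_used = test$test_used,
                 min_expected_count = test$min_expected_count),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR (95%% CI) = %.2f (%.2f to %.2f), p = %.4g [%s, min expected %.1f]\n",
              round_half_up(x$or_estimate), round_half_up(x$ci_low),
              round_half_up(x$ci_high), x$p_value, x$test_used,
              x$min_expected_count))
  print(x$counts)
  invisible(x)
}
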