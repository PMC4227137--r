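# The 2x2 fixtures below are the published training- and test-cohort
# classification counts (nulliparous negative/positive, parous
# negative/positive); the expected ORs, intervals and p-values are the
# printed report values, reproduced at 2 decimal places.

published_tables <- list(
  training_main = list(counts = c(37, 17, 27, 49), or = 3.95,
                       ci = c(1.88, 8.29), p = 2e-04, test = "chi2"),
  training_shl = list(counts = c(22, 32, 45, 31), or = 0.47,
                      ci = c(0.23, 0.96), p = NA, test = "chi2"),
  training_uich = list(counts = c(33, 21, 30, 46), or = 2.41,
                       ci = c(1.18, 4.92), p = 0.015, test = "chi2"),
  adjacent_all = list(counts = c(17, 13, 58, 61), or = 1.38,
                      ci = c(0.61, 3.08), p = NA, test = "chi2"),
  tumor_all = list(counts = c(16, 14, 58, 61), or = 1.20,
                   ci = c(0.54, 2.68), p = 0.65, test = "chi2"),
  adjacent_erpos = list(counts = c(16, 10, 46, 44), or = 1.53,
                        ci = c(0.63, 3.73), p = NA, test = "chi2"),
  adjacent_erneg = list(counts = c(1, 3, 12, 16), or = 0.44,
                        ci = c(0.04, 4.82), p = 0.63, test = "fisher"),
  tumor_erneg = list(counts = c(1, 3, 8, 20), or = 0.83,
                     ci = c(0.07, 9.25), p = 1.00, test = "fisher"))

test_that("odds ratios and Wald intervals reproduce the published values", {
  for (name in names(published_tables)) {
    case <- published_tables[[name]]
    t <- do.call(contingency_table, as.list(case$counts))
    res <- associate(t)
    # within half a printing unit (0.0055 absorbs one truncated-rather-
    # than-rounded published bound, 0.075 -> "0.07")
    expect_lt(abs(res$or_estimate - case$or), 0.0055,
              label = paste(name, "OR"))
    expect_lt(max(abs(c(res$ci_low, res$ci_high) - case$ci)), 0.0055,
              label = paste(name, "CI"))
    expect_identical(res$test_used, case$test)
    if (!is.na(case$p)) {
      digits <- nchar(sub(".*\\.", "", format(case$p, scientific = FALSE)))
      expect_equal(round(res$p_value, digits), case$p, tolerance = 1e-9,
                   label = paste(name, "p"))
    }
  }
})

test_that("symmetric tables give OR 1 and row swap inverts the OR", {
  t <- contingency_table(10, 10, 10, 10)
  expect_equal(odds_ratio(t), 1)
  set.seed(6)
  for (i in 1:20) {
    counts <- sample(1:30, 4, replace = TRUE)
    t <- do.call(contingency_table, as.list(counts))
    swapped <- contingency_table(counts[3], counts[4], counts[1], counts[2])
    expect_equal(odds_ratio(t) * odds_ratio(swapped), 1, tolerance = 1e-12)
  }
})

test_that("Wald interval width shrinks monotonically with n", {
  widths <- sapply(c(5, 20, 80, 320), function(n) {
    ci <- wald_ci(contingency_table(n, n, n, n))
    log(ci[2]) - log(ci[1])
  })
  expect_true(all(diff(widths) < 0))
})

test_that("chi-square path agrees with the closed form", {
  set.seed(7)
  for (i in 1:20) {
    counts <- sample(5:50, 4, replace = TRUE)
    t <- do.call(contingency_table, as.list(counts))
    res <- association_test(t)
    if (res$test_used != "chi2") next
    a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
    n <- sum(counts)
    chi2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$p_value, pchisq(chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Fisher path agrees with exhaustive enumeration (totals <= 60)", {
  set.seed(8)
  checked <- 0L
  while (checked < 25L) {
    counts <- sample(0:15, 4, replace = TRUE)
    if (sum(counts) > 60 || sum(counts) == 0) next
    t <- do.call(contingency_table, as.list(counts))
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    res <- association_test(t)
    if (res$test_used != "fisher") next
    expect_equal(res$p_value, min(fisher_oracle(t), 1), tolerance = 1e-12)
    checked <- checked + 1L
  }
})

test_that("test selection follows the expected-count rule", {
  big <- contingency_table(20, 20, 20, 20)
  expect_identical(association_test(big)$test_used, "chi2")
  small <- contingency_table(1, 3, 12, 16)
  res <- association_test(small)
  expect_identical(res$test_used, "fisher")
  expect_lt(res$min_expected_count, 5)
  expect_gte(association_test(big)$min_expected_count, 5)
})

test_that("zero cells and zero margins are handled explicitly", {
  t0 <- contingency_table(0, 5, 8, 9)
  expect_error(odds_ratio(t0), "haldane")
  expect_true(is.finite(odds_ratio(t0, haldane = TRUE)))
  expect_true(all(is.finite(wald_ci(t0, haldane = TRUE))))
  margin0 <- contingency_table(0, 0, 8, 9)
  expect_warning(res <- association_test(margin0), "zero margin")
  expect_true(is.na(res$p_value))
  expect_identical(res$test_used, "undefined")
})

test_that("counts built from call/parity vectors land in the right cells", {
  calls <- c("negative", "positive", "positive", "negative", "positive")
  parity <- c("nulliparous", "nulliparous", "parous", "parous", "parous")
  t <- contingency_table(calls = calls, parity = parity)
  expect_equal(unname(t["nulliparous", "negative"]), 1L)
  expect_equal(unname(t["nulliparous", "positive"]), 1L)
  expect_equal(unname(t["parous", "negative"]), 1L)
  expect_equal(unname(t["parous", "positive"]), 2L)
})
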