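long <- function(...) {
  gs <- list(...)
  tibble::tibble(value = unlist(gs),
                 group = rep(names(gs), lengths(gs)))
}

test_that("identical group distributions give H = 0 and p = 1", {
  res <- kruskal_wallis(long(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$h_statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("small-sample p-values come from exact enumeration", {
  res <- kruskal_wallis(long(a = c(1, 2), b = c(10, 11)))
  expect_equal(res$method, "exact permutation")
  expect_equal(res$p_value, 1 / 3)
  # independent brute-force enumeration on random data, n_total <= 8
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4)
    res <- kruskal_wallis(long(a = x, b = y))
    expect_equal(res$p_value, oracle_kw_exact_2g(x, y), tolerance = 1e-12)
  }
})

test_that("all-identical pooled values are flagged degenerate with p = 1", {
  res <- kruskal_wallis(long(a = c(5, 5), b = c(5, 5, 5)))
  expect_equal(res$method, "degenerate")
  expect_equal(res$p_value, 1)
  expect_equal(res$h_statistic, 0)
})

test_that("H agrees with the base-R implementation on random tied data", {
  set.seed(32)
  for (i in 1:10) {
    v <- sample(1:8, 30, replace = TRUE) # heavy ties
    g <- rep(c("a", "b", "c"), each = 10)
    ours <- kruskal_wallis(tibble::tibble(value = v, group = g))
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(ours$h_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(33)
  d <- tibble::tibble(value = rnorm(45), group = rep(letters[1:3], each = 15))
  h1 <- kruskal_wallis(d, value, group)$h_statistic
  d2 <- dplyr::mutate(d, value = exp(value))
  d3 <- dplyr::mutate(d, value = 2 * atan(value) - 5)
  expect_equal(kruskal_wallis(d2, value, group)$h_statistic, h1)
  expect_equal(kruskal_wallis(d3, value, group)$h_statistic, h1)
})

test_that("for 2 untied groups H matches the normalized Mann-Whitney statistic", {
  set.seed(34)
  x <- rnorm(12); y <- rnorm(15)
  h <- kruskal_wallis(long(a = x, b = y), exact_max = 0)$h_statistic
  u <- unname(suppressWarnings(stats::wilcox.test(x, y))$statistic)
  n1 <- 12; n2 <- 15; n <- n1 + n2
  h_from_u <- 12 / (n1 * n2 * (n + 1)) * (u - n1 * n2 / 2)^2
  expect_equal(h, h_from_u, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies by the pair count and caps at 1", {
  set.seed(35)
  d2 <- long(a = rnorm(6), b = rnorm(6) + 3)
  r2 <- pairwise_bonferroni(d2)
  expect_equal(r2$n_pairs, 1)
  expect_equal(r2$pairwise$adjusted_p, r2$pairwise$raw_p)

  d4 <- tibble::tibble(value = rnorm(24), group = rep(letters[1:4], each = 6))
  r4 <- pairwise_bonferroni(d4)
  expect_equal(r4$n_pairs, 6)
  expect_equal(r4$pairwise$adjusted_p, pmin(1, 6 * r4$pairwise$raw_p))
})

test_that("stars follow the printed legend thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(c(0.05, 0.01)), c("ns", "*")) # strict inequalities
})

test_that("glance and tidy expose the omnibus and pairwise tables", {
  set.seed(36)
  d <- tibble::tibble(value = rnorm(30), group = rep(c("a", "b", "c"), each = 10))
  cmp <- pairwise_bonferroni(d)
  expect_equal(nrow(tidy(cmp)), 3)
  expect_equal(glance(cmp)$n_pairs, 3)
  expect_true(all(tidy(cmp)$stars %in% c("ns", "*", "**", "***", "****")))
})

test_that("box summaries use type-7 quartiles and 1.5 IQR whiskers", {
  b <- box_summary(1:7)
  expect_equal(b$median, 4)
  expect_equal(b$q1, 2.5)
  expect_equal(b$q3, 5.5)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 7)
  expect_equal(b$outliers[[1]], numeric(0))

  flat <- box_summary(c(1, 1, 1, 1))
  expect_true(all(c(flat$median, flat$q1, flat$q3,
                    flat$whisker_low, flat$whisker_high) == 1))

  out <- box_summary(c(1, 2, 3, 100))
  expect_equal(out$outliers[[1]], 100)
  expect_equal(out$whisker_high, 3)

  single <- box_summary(5)
  expect_equal(single$median, 5)
})

test_that("grouping preconditions are enforced", {
  expect_error(kruskal_wallis(tibble::tibble(value = 1:3, group = "a")), "2 groups")
  expect_error(kruskal_wallis(long(a = 1, b = c(2, 3))), ">= 2 values")
  expect_error(kruskal_wallis(long(a = c(1, NA), b = c(2, 3))), "finite")
})

test_that("Dunn's test option produces valid adjusted p-values", {
  set.seed(37)
  d <- tibble::tibble(value = c(rnorm(10), rnorm(10) + 2, rnorm(10)),
                      group = rep(c("a", "b", "c"), each = 10))
  cmp <- pairwise_bonferroni(d, method = "dunn")
  expect_true(all(cmp$pairwise$raw_p >= 0 & cmp$pairwise$raw_p <= 1))
  pw <- cmp$pairwise
  expect_lt(pw$adjusted_p[pw$group1 == "b" & pw$group2 == "c"], 0.05)
  expect_equal(pw$stars[pw$group1 == "a" & pw$group2 == "c"], "ns")
})
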