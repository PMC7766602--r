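# Nonparametric comparison machinery: Kruskal-Wallis omnibus (exact
# permutation branch for very small totals), pairwise Mann-Whitney with
# Bonferroni correction, and 1.5*IQR box-plot summaries.

as_grouped <- function(data, value, group) {
  data <- tibble::as_tibble(data)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  if (!is.numeric(v)) stop("value column must be numeric", call. = FALSE)
  if (any(!is.finite(v))) stop("all values must be finite", call. = FALSE)
  groups <- split(v, factor(g, levels = unique(g)))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  groups
}

# Tie-corrected Kruskal-Wallis H from a pooled value vector and group sizes.
kw_h <- function(values, sizes) {
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(sizes), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(NA_real_) # all values identical
  h / corr
}

# Enumerate all assignments of n items into groups of the given sizes
# (combinations, not permutations). Returns a list of index lists.
enumerate_partitions <- function(n, sizes) {
  out <- list()
  recur <- function(remaining, sizes_left, acc) {
    if (length(sizes_left) == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    if (length(sizes_left) == 1) {
      out[[length(out) + 1]] <<- c(acc, list(remaining))
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    for (p in picks) recur(setdiff(remaining, p), sizes_left[-1], c(acc, list(p)))
  }
  recur(seq_len(n), sizes, list())
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution
#' (`k - 1` degrees of freedom). For small studies (total n at or below
#' `exact_max`) the p-value is computed exactly by enumerating every
#' assignment of the pooled values to groups of the observed sizes and
#' counting assignments with H at least as large as observed. If all pooled
#' values are identical the comparison is degenerate and `p = 1` is reported
#' with a flag.
#'
#' @param data tibble in long format.
#' @param value,group column names (tidy-eval).
#' @param exact_max largest total n for the exact permutation branch
#'   (default 10).
#' @return One-row tibble: `h_statistic`, `df`, `p_value`, `n_total`,
#'   `n_groups`, `method` (`"chi-squared"`, `"exact permutation"` or
#'   `"degenerate"`).
#' @export
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 10, 11), g = c("a", "a", "b", "b"))
#' kruskal_wallis(d, v, g) # exact p = 1/3
kruskal_wallis <- function(data, value = value, group = group, exact_max = 10) {
  groups <- as_grouped(data, {{ value }}, {{ group }})
  sizes <- vapply(groups, length, 0L)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  k <- length(groups)

  h <- kw_h(pooled, sizes)
  if (is.na(h)) {
    return(tibble::tibble(h_statistic = 0, df = k - 1, p_value = 1,
                          n_total = n, n_groups = k, method = "degenerate"))
  }
  if (n <= exact_max) {
    parts <- enumerate_partitions(n, sizes)
    hs <- vapply(parts, function(p) {
      kw_h(pooled[unlist(p)], sizes)
    }, numeric(1))
    p <- mean(hs >= h - 1e-12)
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi-squared"
  }
  tibble::tibble(h_statistic = h, df = k - 1, p_value = p,
                 n_total = n, n_groups = k, method = method)
}

#' Significance stars at the conventional thresholds
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Pairwise group comparison with Bonferroni correction
#'
#' Kruskal-Wallis omnibus followed by all pairwise two-sided rank tests with
#' Bonferroni adjustment `p_adj = min(1, m * p_raw)` over the `m` pairs.
#' The pairwise test is Mann-Whitney U by default; `method = "dunn"` uses
#' Dunn's z test on the pooled ranks instead.
#'
#' @param data tibble in long format.
#' @param value,group column names (tidy-eval).
#' @param method `"mann-whitney"` (default) or `"dunn"`.
#' @return An object of class `comparison_result` with the omnibus tibble and
#'   a `pairwise` tibble (`group1`, `group2`, `raw_p`, `adjusted_p`,
#'   `stars`).
#' @export
pairwise_bonferroni <- function(data, value = value, group = group,
                                method = c("mann-whitney", "dunn")) {
  method <- match.arg(method)
  groups <- as_grouped(data, {{ value }}, {{ group }})
  omnibus <- kruskal_wallis(data, {{ value }}, {{ group }})
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)

  raw_p <- vapply(pairs, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (length(unique(c(x, y))) == 1) return(1)
    if (method == "mann-whitney") {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    } else {
      dunn_p(groups, pr)
    }
  }, numeric(1))
  adjusted <- stats::p.adjust(raw_p, method = "bonferroni")

  pairwise <- tibble::tibble(
    group1 = vapply(pairs, `[`, "", 1),
    group2 = vapply(pairs, `[`, "", 2),
    raw_p = raw_p, adjusted_p = adjusted, stars = p_stars(adjusted)
  )
  structure(list(omnibus = omnibus, pairwise = pairwise, method = method,
                 n_pairs = m),
            class = "comparison_result")
}

# Dunn's pairwise z test on pooled midranks with tie correction.
dunn_p <- function(groups, pair) {
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(names(groups), vapply(groups, length, 0L))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  m1 <- mean(r[idx == pair[1]]); m2 <- mean(r[idx == pair[2]])
  n1 <- length(groups[[pair[1]]]); n2 <- length(groups[[pair[2]]])
  se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
  z <- (m1 - m2) / se
  2 * stats::pnorm(-abs(z))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> Kruskal-Wallis H = %.4g, p = %.4g (%s)\n",
              x$omnibus$h_statistic, x$omnibus$p_value, x$omnibus$method))
  cat(sprintf("  %d pairwise %s tests, Bonferroni m = %d\n",
              nrow(x$pairwise), x$method, x$n_pairs))
  print(x$pairwise)
  invisible(x)
}

#' Tidy pairwise comparison results
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return The pairwise tibble.
#' @export
tidy.comparison_result <- function(x, ...) x$pairwise

#' One-row omnibus summary
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return The omnibus tibble with `n_pairs` appended.
#' @export
glance.comparison_result <- function(x, ...) {
  dplyr::mutate(x$omnibus, n_pairs = x$n_pairs)
}

#' Box-plot summary with 1.5 IQR whiskers
#'
#' Quartiles by linear interpolation (type 7); whiskers extend to the most
#' extreme data points within 1.5 interquartile ranges of the quartiles;
#' points beyond are listed as outliers.
#'
#' @param values numeric vector (at least 1 value).
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers` (list column).
#' @export
#' @examples
#' box_summary(c(1, 2, 3, 100))
box_summary <- function(values) {
  if (length(values) < 1) stop("need at least 1 value", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble::tibble(
    n = length(values), median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]), whisker_high = max(values[inside]),
    outliers = list(sort(values[!inside]))
  )
}

#' Box-plot panel of grouped measurements
#'
#' @param data long-format tibble.
#' @param value,group column names (tidy-eval).
#' @return A ggplot object: 1.5 IQR box plots with individual points
#'   overlaid (one dot per measurement, e.g. per capillary).
#' @export
plot_group_boxes <- function(data, value = value, group = group) {
  data <- tibble::as_tibble(data)
  ggplot2::ggplot(data, ggplot2::aes(x = factor({{ group }}), y = {{ value }})) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
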