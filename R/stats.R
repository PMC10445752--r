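# Statistical primitives shared by every stage of the pipeline. These are
# thin, contract-fixing wrappers over base R tests: the value added is that
# the tail conventions (e.g. P(X >= k) for over-representation) and option
# defaults (Yates correction, exact-vs-approximate Wilcoxon switching) are
# decided once, here, and verified against enumeration oracles in the tests.

#' Construct a test result
#'
#' Lightweight container for a statistic and p-value with the tail and method
#' recorded, used by every hypothesis test in the package.
#'
#' @param statistic Numeric test statistic.
#' @param p_value P-value in \[0, 1\].
#' @param tail One of `"greater"`, `"less"`, `"two-sided"`.
#' @param method Short method label.
#' @return A list of class `test_result`.
#' @keywords internal
new_test_result <- function(statistic, p_value, tail, method) {
  p_value <- unname(p_value)
  if (is.na(p_value) || p_value < -1e-12 || p_value > 1 + 1e-12) {
    validation_error("p-value out of [0, 1]: ", p_value)
  }
  structure(
    list(
      statistic = unname(statistic),
      p_value = min(max(p_value, 0), 1),
      tail = tail,
      method = method
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s tail): statistic = %.6g, p = %.6g\n",
              x$method, x$tail, x$statistic, x$p_value))
  invisible(x)
}

#' Hypergeometric overlap test
#'
#' Tail probability for the overlap of two sets drawn from a finite universe,
#' the workhorse for marker-overlap, ORA and TF-family co-occurrence tests.
#' `tail = "greater"` returns P(X >= overlap) (over-representation);
#' `tail = "less"` returns P(X <= overlap), where
#' X ~ Hypergeometric(universe, set_a, set_b).
#'
#' @param overlap Observed overlap count.
#' @param set_a,set_b Sizes of the two sets.
#' @param universe Universe size.
#' @param tail `"greater"` or `"less"`.
#' @return A `test_result`; `statistic` is the observed overlap.
#' @export
hypergeom_overlap <- function(overlap, set_a, set_b, universe,
                              tail = c("greater", "less")) {
  tail <- match.arg(tail)
  for (v in list(overlap, set_a, set_b, universe)) {
    if (!is_count(v)) validation_error("all counts must be non-negative integers")
  }
  if (overlap > min(set_a, set_b)) {
    validation_error("overlap (", overlap, ") exceeds min(set_a, set_b)")
  }
  if (set_a > universe || set_b > universe) {
    validation_error("set sizes must not exceed the universe")
  }
  p <- if (tail == "greater") {
    stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                  lower.tail = FALSE)
  } else {
    stats::phyper(overlap, set_a, universe - set_a, set_b, lower.tail = TRUE)
  }
  new_test_result(overlap, p, tail, "hypergeometric")
}

#' One-sided Fisher's exact test (greater)
#'
#' One-sided p-value summing the hypergeometric tail of 2x2 tables at least
#' as extreme in the (1,1) cell, as used for the ChIP-seq and H3K27ac
#' overlap tests.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `test_result`; `statistic` is the conditional odds-ratio MLE.
#' @export
fisher_greater <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != floor(table))) {
    validation_error("table must be a 2x2 matrix of non-negative integers")
  }
  ft <- stats::fisher.test(table, alternative = "greater")
  new_test_result(unname(ft$estimate), ft$p.value, "greater", "fisher_exact")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test comparing two samples, used for expression-by-peak
#' -count comparisons. Uses the exact null distribution when the combined
#' sample size is at most `exact_max_n` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max_n Largest combined sample size for the exact path.
#' @return A `test_result`; `statistic` is the rank-sum statistic W.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20) {
  if (length(x) == 0 || length(y) == 0) {
    validation_error("both samples must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- wt$p.value
  if (is.na(p)) p <- 1   # fully tied samples: no evidence of a shift
  new_test_result(unname(wt$statistic), p, "two-sided",
                  if (exact) "wilcoxon_exact" else "wilcoxon_normal")
}

#' One-sided two-proportion test (p1 > p2)
#'
#' Chi-square test with Yates continuity correction following the
#' `prop.test` contract, used to compare conservation proportions between
#' peak sets.
#'
#' @param x1,n1 Successes and trials in the first group.
#' @param x2,n2 Successes and trials in the second group.
#' @return A `test_result`; `statistic` is the chi-squared statistic.
#' @export
two_proportion_greater <- function(x1, n1, x2, n2) {
  if (!is_count(x1) || !is_count(n1) || !is_count(x2) || !is_count(n2) ||
      x1 > n1 || x2 > n2 || n1 == 0 || n2 == 0) {
    validation_error("need x1 <= n1, x2 <= n2 with n1, n2 > 0")
  }
  if (x1 + x2 == 0 || x1 + x2 == n1 + n2) {
    # degenerate pooled proportion: the proportions are equal, no signal
    return(new_test_result(0, 1, "greater", "two_proportion_yates"))
  }
  pt <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), alternative = "greater",
                     correct = TRUE)
  )
  new_test_result(unname(pt$statistic), pt$p.value, "greater",
                  "two_proportion_yates")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; order-preserving with the input and
#' clipped to 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    validation_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value from
#' the t approximation, used to check the coupling between accessibility-
#' derived gene activity and expression.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `test_result`; `statistic` is rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    validation_error("x and y must have equal length >= 3")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    validation_error("rho undefined: zero variance in ranks")
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test_result(rho, p, "two-sided", "spearman_t")
}
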