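# Statistical kernel: multiple-testing adjustment, the signed significance
# metric plotted against variant classes, one-tailed Mann-Whitney U, Fisher's
# exact test, chi-square goodness of fit, and fold-enrichment arithmetic.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (p * n / rank with cumulative-min
#' monotonicity enforcement, capped at 1); output order matches input.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  assert_probability(p)
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)` elementwise, where `m` is the total number of tests in the
#' family (for eQTL tables: all genotype-gene associations tested), which may
#' exceed the number of p-values at hand.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Total number of tests; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m) {
  assert_probability(p)
  if (!(is.numeric(m) && length(m) == 1 && m >= length(p))) {
    stop("m must be a single number >= length(p)", call. = FALSE)
  }
  pmin(1, p * m)
}

#' Direction-signed -log10 adjusted p
#'
#' The per-variant metric plotted against variant classes: positive for
#' expression increases, negative for decreases, magnitude -log10(p_adj).
#'
#' @param p_adj Adjusted p-values in (0, 1\]; zeros are clamped to `floor`
#'   with a warning.
#' @param direction Character vector over `"up"`, `"down"`, `"none"`
#'   (`"none"`, for zero effects, maps to 0).
#' @param floor Lower clamp applied before the log (default 1e-300).
#' @return Numeric vector of signed -log10 values.
#' @export
signed_logp <- function(p_adj, direction, floor = 1e-300) {
  assert_probability(p_adj, "p_adj")
  if (length(direction) != length(p_adj)) {
    direction <- rep_len(direction, length(p_adj))
  }
  if (!all(direction %in% c("up", "down", "none"))) {
    stop("direction must be 'up', 'down' or 'none'", call. = FALSE)
  }
  if (any(p_adj < floor)) {
    warning(sprintf("%d p_adj value(s) below %g clamped before log",
                    sum(p_adj < floor), floor))
    p_adj <- pmax(p_adj, floor)
  }
  sgn <- c(up = 1, down = -1, none = 0)[direction]
  unname(sgn * -log10(p_adj))
}

#' Is a variant gain-of-function?
#'
#' GOF means a significant increase in expression: adjusted p strictly below
#' `alpha` and direction `"up"`.
#'
#' @param p_adj Adjusted p-values.
#' @param direction `"up"` / `"down"` / `"none"`.
#' @param alpha Significance level (default 0.05; strict inequality).
#' @return Logical vector.
#' @export
is_gof <- function(p_adj, direction, alpha = 0.05) {
  assert_probability(p_adj, "p_adj")
  p_adj < alpha & direction == "up"
}

#' One-tailed Mann-Whitney U test (a stochastically greater than b)
#'
#' Exact p by enumeration when `n_a * n_b <= exact_limit` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. The reported `U` is the statistic for group a.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Product-of-sizes bound for the exact path (default 400).
#' @return A `mwu_result` list: `n_a`, `n_b`, `U`, `p_one_tailed`, `method`.
#' @export
#' @examples
#' mwu_one_tailed(c(3, 4, 5), c(1, 2))  # U = 6, p = 0.1
mwu_one_tailed <- function(a, b, exact_limit = 400) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("NA values in groups", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) * length(b) <= exact_limit
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater",
                       exact = use_exact, correct = TRUE)
  )
  structure(list(n_a = length(a), n_b = length(b),
                 U = unname(res$statistic), p_one_tailed = res$p.value,
                 method = if (use_exact) "exact" else "normal_approx"),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (one-tailed, greater): U = %g, n = %d vs %d, p = %.4g [%s]\n",
              x$U, x$n_a, x$n_b, x$p_one_tailed, x$method))
  invisible(x)
}

#' Fisher's exact test on a 2 x k contingency table
#'
#' Two-sided exact p over tables with the observed margins, summing the
#' probabilities of tables no more probable than the observed one. Used for
#' phenotype-by-line comparisons (k up to 9) and GOF-count 2 x 2 tables.
#'
#' @param tab Integer matrix with 2 rows and at most 9 columns (or the
#'   transpose), non-negative counts, no all-zero margin.
#' @return The two-sided p-value.
#' @export
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(tab == round(tab)) || any(tab < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (min(dim(tab)) != 2 || max(dim(tab)) > 9) {
    stop("table must be 2 x k with k <= 9", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has an all-zero margin", call. = FALSE)
  }
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

#' Chi-square goodness of fit
#'
#' Pearson statistic against stated expected proportions, k - 1 degrees of
#' freedom (e.g. laterality counts against a 50/50 left-right expectation).
#'
#' @param observed Non-negative integer counts, total > 0.
#' @param expected_props Expected proportions summing to 1, all > 0.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_gof <- function(observed, expected_props) {
  if (length(observed) != length(expected_props)) {
    stop("observed and expected_props must have the same length", call. = FALSE)
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed must be non-negative counts with a positive total", call. = FALSE)
  }
  if (any(expected_props <= 0)) stop("expected proportions must all be > 0", call. = FALSE)
  if (abs(sum(expected_props) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(observed, p = expected_props))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Fold enrichment of a subset rate over the overall rate
#'
#' E.g. the GOF rate among affinity-optimizing SNVs divided by the GOF rate
#' among all SNVs. When the underlying 2 x 2 counts are supplied
#' (`rbind(c(subset_hits, subset_misses), c(rest_hits, rest_misses))`),
#' Fisher's exact p on them is attached.
#'
#' @param rate_subset,rate_all Rates in \[0, 1\]; `rate_all` must be > 0.
#' @param counts Optional 2 x 2 count matrix for the exact test.
#' @return list with `fold`, `rate_subset`, `rate_all`, `fisher_p` (NA when
#'   no counts given).
#' @export
#' @examples
#' fold_enrichment(0.36, 0.145)$fold  # ~2.5
fold_enrichment <- function(rate_subset, rate_all, counts = NULL) {
  if (!is.numeric(rate_all) || rate_all <= 0) {
    stop("rate_all must be > 0", call. = FALSE)
  }
  fisher_p <- NA_real_
  if (!is.null(counts)) fisher_p <- fisher_exact_2xk(counts)
  list(fold = rate_subset / rate_all,
       rate_subset = rate_subset, rate_all = rate_all,
       fisher_p = fisher_p)
}

# Box-plot summary numbers (quartiles plus 1.5 x IQR whisker bounds), the
# numeric equivalent of the figures' box plots.
box_stats <- function(x) {
  if (length(x) == 0) {
    return(list(n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  list(n = length(x), q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = lo, whisker_high = hi)
}
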