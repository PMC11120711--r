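#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Association between mutation frequency and a binary grouping (tumor grade
#' or morphological pattern). The two-sided p-value follows the
#' probability-mass rule: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table. Computation is delegated to [stats::fisher.test()],
#' which implements exactly this definition; the package's test suite checks
#' it against direct hypergeometric enumeration.
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = groups,
#'   columns = mutant / wild type).
#' @return Two-sided p-value. Degenerate tables with an empty margin return
#'   `p = 1` with a warning.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must be a 2x2 matrix of nonnegative counts", call. = FALSE)
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: p = 1 by convention", call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test with Bonferroni correction
#'
#' Rank-sum comparison of two stiffness samples. Ties are handled by
#' midranks. The exact permutation distribution is used for small samples
#' (combined n <= `exact_max`, no ties); otherwise the normal approximation
#' with tie correction and continuity correction 0.5 is used. The Bonferroni
#' adjusted p-value is `min(1, m * p)` for `m = n_comparisons`.
#'
#' @param sample_a,sample_b Numeric vectors (kPa), non-empty.
#' @param n_comparisons Bonferroni `m` (number of tests in the family).
#' @param exact `TRUE`/`FALSE` to force a mode, or `NULL` for the size rule.
#' @param exact_max Combined-sample-size bound for the exact mode.
#' @return A list: `u_statistic` (U of `sample_a`), `p_two_sided`,
#'   `p_adjusted`, `method`.
#' @export
mann_whitney <- function(sample_a, sample_b, n_comparisons = 1L,
                         exact = NULL, exact_max = 12L) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  if (is.null(exact))
    exact <- (length(sample_a) + length(sample_b) <= exact_max) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  p <- wt$p.value
  list(u_statistic = unname(wt$statistic),
       p_two_sided = p,
       p_adjusted = min(1, n_comparisons * p),
       method = if (exact && !ties) "exact" else "normal-approx-tie-corrected")
}

#' Group summaries and pairwise Mann-Whitney tests
#'
#' Descriptive statistics (n, mean, sd, min, max of ROI stiffness) per group
#' plus all pairwise Mann-Whitney U tests with Bonferroni correction, `m` =
#' number of pairs. Groups are ordered by label; empty groups are omitted
#' with a warning.
#'
#' @param cohort An [sample_cohort()] table.
#' @param group_by `"pattern"`, `"mutation"` (mutant vs wild type), or
#'   `"pattern_mutation"` (their interaction).
#' @return A list: `summary` data.frame (one row per group) and `tests`
#'   data.frame (one row per pair: `group_a`, `group_b`, `u_statistic`,
#'   `p_two_sided`, `p_adjusted`, `m`).
#' @export
summarize_groups <- function(cohort,
                             group_by = c("pattern", "mutation",
                                          "pattern_mutation")) {
  group_by <- match.arg(group_by)
  g <- switch(group_by,
              pattern = cohort$pattern,
              mutation = ifelse(cohort$mutation == "wt", "wildtype", "mutant"),
              pattern_mutation = paste(
                cohort$pattern,
                ifelse(cohort$mutation == "wt", "wildtype", "mutant"),
                sep = ":"))
  labs <- sort(unique(g))
  keep <- vapply(labs, function(l) sum(g == l) > 0, logical(1))
  if (!all(keep)) warning("omitting empty groups", call. = FALSE)
  labs <- labs[keep]
  summ <- do.call(rbind, lapply(labs, function(l) {
    x <- cohort$stiffness_kpa[g == l]
    data.frame(group = l, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(labs) > 1) {
    pairs <- utils::combn(labs, 2)
    m <- ncol(pairs)
    tests <- do.call(rbind, lapply(seq_len(m), function(i) {
      a <- cohort$stiffness_kpa[g == pairs[1, i]]
      b <- cohort$stiffness_kpa[g == pairs[2, i]]
      r <- mann_whitney(a, b, n_comparisons = m)
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                 u_statistic = r$u_statistic, p_two_sided = r$p_two_sided,
                 p_adjusted = r$p_adjusted, m = m, method = r$method,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, tests = tests)
}
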