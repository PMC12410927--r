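#' Pseudotime accuracy: Pearson, Spearman, and Kendall correlations
#'
#' Correlates an inferred ordering with ground truth. Kendall's tau is
#' computed by the pairwise-sign formula
#' `tau = 1/(n(n-1)) * sum_{i != j} sgn(x_i - x_j) sgn(y_i - y_j)`
#' (ordered pairs, no tie correction: tied pairs drop out of the numerator
#' while the denominator keeps all n(n-1) pairs). The standard
#' tie-corrected tau-b is reported alongside as `kendall_b`.
#'
#' @param estimate,truth numeric vectors of equal length `n >= 3`, no
#'   missing values.
#' @return Named list with `pearson`, `spearman`, `kendall` (pairwise-sign
#'   formula), and `kendall_b`. Correlations against a constant vector are
#'   undefined and reported as `NaN` with a warning.
#' @export
correlations <- function(estimate, truth) {
  if (length(estimate) != length(truth)) stop("`estimate` and `truth` must have equal length")
  if (length(estimate) < 3) stop("need at least 3 observations")
  if (anyNA(estimate) || anyNA(truth)) stop("missing values are not allowed")
  if (stats::sd(estimate) == 0 || stats::sd(truth) == 0) {
    warning("constant vector: correlations are undefined (NaN)")
    return(list(pearson = NaN, spearman = NaN, kendall = NaN, kendall_b = NaN))
  }
  n <- length(estimate)
  sx <- sign(outer(estimate, estimate, "-"))
  sy <- sign(outer(truth, truth, "-"))
  kendall <- sum(sx * sy) / (n * (n - 1))
  list(pearson = stats::cor(estimate, truth),
       spearman = stats::cor(estimate, truth, method = "spearman"),
       kendall = kendall,
       kendall_b = stats::cor(estimate, truth, method = "kendall"))
}

#' Per-branch precision, recall, and F1
#'
#' Treats membership of one terminal branch as a binary classification
#' task: TP are cells correctly predicted in the branch, FP cells wrongly
#' predicted in it, FN cells of the branch assigned elsewhere (including
#' cells left as progenitors). Zero denominators yield 0 by convention.
#'
#' @param predicted,truth label vectors over a shared alphabet; `predicted`
#'   may contain a progenitor sentinel (`"progenitor"` or 0), which counts
#'   as "not this branch" for every terminal branch.
#' @param branch the target branch label.
#' @return List with `branch`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
branch_f1 <- function(predicted, truth, branch) {
  if (length(predicted) != length(truth)) stop("`predicted` and `truth` must have equal length")
  pin <- predicted == branch
  tin <- truth == branch
  tp <- sum(pin & tin)
  fp <- sum(pin & !tin)
  fn <- sum(!pin & tin)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(branch = branch, tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Group tests on differentiation potential
#'
#' Global Kruskal-Wallis test of DP differences across cell states, plus
#' one-tailed Mann-Whitney U tests for each ordered (earlier, later) state
#' pair, testing whether the earlier state has *higher* differentiation
#' potential. For two groups the MWU test is the two-group special case of
#' the KW test. Small groups (both sides <= 20, no ties) use the exact U
#' distribution; larger ones the normal approximation with tie correction.
#'
#' @param dp numeric differentiation-potential scores.
#' @param labels group labels, one per score; every group needs >= 2
#'   members.
#' @param ordered_pairs list of `c(earlier, later)` label pairs to test.
#' @return List with `kw_statistic`, `kw_p`, and a data.frame `pairs`
#'   (`earlier`, `later`, `mwu_p`).
#' @export
dp_group_tests <- function(dp, labels, ordered_pairs = list()) {
  if (length(dp) != length(labels)) stop("`dp` and `labels` must have equal length")
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  small <- names(tab)[tab < 2]
  if (length(small)) stop(sprintf("group '%s' has fewer than 2 members", small[1]))
  kw <- stats::kruskal.test(dp, factor(labels))
  pairs <- NULL
  for (pr in ordered_pairs) {
    if (!all(pr %in% names(tab))) stop(sprintf("unknown group in pair (%s, %s)", pr[1], pr[2]))
    x <- dp[labels == pr[1]]
    y <- dp[labels == pr[2]]
    use_exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
    w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                             exact = use_exact, correct = FALSE))
    pairs <- rbind(pairs, data.frame(earlier = pr[1], later = pr[2],
                                     mwu_p = w$p.value, stringsAsFactors = FALSE))
  }
  list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value, pairs = pairs)
}
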