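#' Per-group metric summaries
#'
#' Median and range per metric per group, the format used to report cohort
#' metrics (e.g. "median SNV burden 3.38, range 0.48-55.53").
#'
#' @param metrics Data frame of per-sample metrics.
#' @param metric_names Character vector of numeric metric columns.
#' @param group_by Optional grouping column name; NULL summarizes the whole
#'   cohort as one group called "all".
#' @return Data frame: `group`, `metric`, `n`, `median`, `min`, `max`.
#' @export
summarize_metrics <- function(metrics,
                              metric_names = c("snv_burden", "indel_burden",
                                               "wgii", "caer",
                                               "cn_amplitude"),
                              group_by = NULL) {
  grp <- if (is.null(group_by)) rep("all", nrow(metrics)) else
    as.character(metrics[[group_by]])
  out <- list()
  for (g in unique(grp)) {
    rows <- metrics[grp == g, , drop = FALSE]
    if (nrow(rows) == 0) { warning("empty group ", g, " omitted"); next }
    for (m in metric_names) {
      v <- rows[[m]]
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = m, n = length(v), median = stats::median(v),
        min = min(v), max = max(v))
    }
  }
  do.call(rbind, out)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all rank assignments (midranks under ties) when both
#' groups have at most `exact_max` observations; otherwise the normal
#' approximation with tie correction via [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest per-group size for the exact path. Default 10.
#' @param correct Continuity correction for the normal approximation.
#'   Default TRUE.
#' @return List: `p_value`, `statistic` (rank sum of `x`), `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10, correct = TRUE) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    e_w <- n * (n + m + 1) / 2
    combs <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
    return(list(p_value = p, statistic = w_obs, method = "exact"))
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = correct)
  list(p_value = wt$p.value, statistic = w_obs, method = "normal")
}

#' Compare one metric between two groups
#'
#' Two-sided rank-sum comparison of a metric between the two levels of a
#' grouping column (e.g. wGII between mGBM and Others, or SNV burden between
#' primary and recurrent tumors).
#'
#' @param metrics Data frame of per-sample metrics.
#' @param metric_name Numeric column to compare.
#' @param grouping Column with exactly two non-empty levels.
#' @param ... Passed to [rank_sum_test()].
#' @return List: `p_value`, `groups`, `medians` (named), `method`.
#' @export
compare_groups <- function(metrics, metric_name, grouping, ...) {
  g <- as.character(metrics[[grouping]])
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping must have exactly two levels, got ",
                             length(lev))
  x <- metrics[[metric_name]][g == lev[1]]
  y <- metrics[[metric_name]][g == lev[2]]
  t <- rank_sum_test(x, y, ...)
  list(p_value = t$p_value, groups = lev,
       medians = stats::setNames(c(stats::median(x), stats::median(y)), lev),
       method = t$method)
}

#' Chi-squared comparison of event prevalence
#'
#' Chi-squared test on a 2 x 2 contingency table of an event flag by group
#' (continuity correction on by default, matching small-sample practice).
#'
#' @param tab 2 x 2 integer matrix, or `flags` + `groups` vectors.
#' @param flags,groups Optional logical event flags and group labels used to
#'   build the table when `tab` is missing.
#' @param correct Continuity correction. Default TRUE.
#' @return List: `p_value`, `statistic`, `table`.
#' @export
compare_prevalence <- function(tab = NULL, flags = NULL, groups = NULL,
                               correct = TRUE) {
  if (is.null(tab)) tab <- table(factor(groups), factor(flags))
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero-margin contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(p_value = ct$p.value, statistic = unname(ct$statistic), table = tab)
}

#' Metric correlogram with two-cluster dendrogram
#'
#' Spearman correlation across the seven metrics (the binary chromothripsis
#' and double-minute flags coded 0/1), hierarchical clustering of the metrics
#' on distance 1 - r with average linkage, cut into two clusters. The expected
#' structure splits the mutational metrics (SNV and indel burden) from the
#' copy-number metrics (wGII, CAER, amplitude, CT, DM).
#'
#' @param metrics Data frame of per-sample metrics (>= 3 rows).
#' @param metric_names Columns to correlate.
#' @param method Correlation method. Default "spearman".
#' @return List: `cor` (matrix), `hclust`, `clusters` (named membership
#'   vector, 2 clusters).
#' @export
metric_correlogram <- function(metrics,
                               metric_names = c("snv_burden", "indel_burden",
                                                "wgii", "caer",
                                                "cn_amplitude", "ct_present",
                                                "dm_present"),
                               method = "spearman") {
  if (nrow(metrics) < 3) stop("need at least 3 samples")
  m <- sapply(metrics[, metric_names, drop = FALSE], as.numeric)
  constant <- apply(m, 2, function(v) stats::var(v) == 0 || !is.finite(stats::var(v)))
  cmat <- suppressWarnings(stats::cor(m, method = method))
  if (any(constant) || anyNA(cmat)) {
    warning("constant metric(s): undefined correlations set to 0")
    cmat[is.na(cmat)] <- 0
    diag(cmat) <- 1
  }
  hc <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
  clusters <- stats::cutree(hc, k = 2)
  list(cor = cmat, hclust = hc, clusters = clusters)
}

#' Pearson correlation of a metric with age
#'
#' @param metrics Data frame with an `age` column.
#' @param metric_name Numeric metric column.
#' @param method Correlation method. Default "pearson".
#' @return List: `r`, `p_value`, `n`.
#' @export
age_correlation <- function(metrics, metric_name, method = "pearson") {
  ok <- is.finite(metrics$age) & is.finite(metrics[[metric_name]])
  x <- metrics$age[ok]; y <- metrics[[metric_name]][ok]
  if (length(x) < 3) stop("need at least 3 samples with age")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = method)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Associate mutated genes with a metric
#'
#' For each gene carrying a high-impact variant in at least `min_group`
#' samples (and wild-type in at least `min_group`), compares the metric
#' between mutated and wild-type samples with the two-sided rank-sum test.
#' Unadjusted p < alpha flags significance by default; Benjamini-Hochberg
#' adjustment is available.
#'
#' @param high_impact Named list, sample id to gene symbols (see
#'   [high_impact_genes()]).
#' @param metrics Data frame with a `sample` column and the metric.
#' @param metric_name Metric column to test.
#' @param alpha Significance level. Default 0.05.
#' @param adjust P-value adjustment method for the `significant` flag
#'   ("none" or "BH"). Default "none".
#' @param min_group Minimum mutated and wild-type group size. Default 2.
#' @return Data frame: `gene`, `metric`, `n_mut`, `n_wt`, `p_value`,
#'   `direction` (+1 mutated higher, -1 lower, 0 tied medians),
#'   `significant`; sorted by p.
#' @export
gene_metric_association <- function(high_impact, metrics, metric_name,
                                    alpha = 0.05, adjust = c("none", "BH"),
                                    min_group = 2) {
  adjust <- match.arg(adjust)
  samples <- metrics$sample
  high_impact <- high_impact[intersect(names(high_impact), samples)]
  genes <- sort(unique(unlist(high_impact)))
  vals <- stats::setNames(metrics[[metric_name]], samples)
  rows <- list()
  for (g in genes) {
    mut <- names(high_impact)[vapply(high_impact, function(x) g %in% x,
                                     logical(1))]
    wt <- setdiff(samples, mut)
    if (length(mut) < min_group || length(wt) < min_group) next
    t <- rank_sum_test(vals[mut], vals[wt])
    d <- sign(stats::median(vals[mut]) - stats::median(vals[wt]))
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, metric = metric_name, n_mut = length(mut), n_wt = length(wt),
      p_value = t$p_value, direction = d)
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), metric = character(),
                      n_mut = integer(), n_wt = integer(),
                      p_value = numeric(), direction = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  p_eff <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$significant <- p_eff < alpha
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
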