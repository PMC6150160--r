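## Group-statistics module: group summaries (mean / SD / SE) and pairwise
## Welch t-tests with the usual significance categories.

## Categories use strict inequalities, matching the printed "p < 0.05"
## notation: a p exactly equal to a threshold falls in the weaker category.
.pCategory <- function(p) {
  if (p < 0.001) "p<0.001"
  else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05"
  else "NS"
}

#' Summarize one treatment group
#'
#' @param group a [GroupMeasurements-class] with at least 2 values, or a
#'   numeric vector.
#' @return A [GroupSummary-class] with the sample mean, the n-1 standard
#'   deviation and the standard error `sd / sqrt(n)`.
#' @examples
#' summarizeGroup(GroupMeasurements("demo", c(0, 2)))
#' @export
summarizeGroup <- function(group) {
  v <- if (is(group, "GroupMeasurements")) group@values else as.numeric(group)
  n <- length(v)
  if (n < 2)
    .invalidArg("a group needs at least 2 values")
  s <- stats::sd(v)
  new("GroupSummary", mean = mean(v), sd = s, se = s / sqrt(n),
      n = as.integer(n))
}

#' Welch t-test from group summaries
#'
#' Two-tailed t-test for independent samples with unequal variances, from
#' summary statistics only:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom. When both SDs are zero the test degenerates: equal
#' means give `p = 1` (NS); unequal means are reported as `p = 0`,
#' category `p<0.001`, with the `degenerate` flag set.
#'
#' @param mean1,sd1,n1 first group's mean, SD and size (`n1 >= 2`).
#' @param mean2,sd2,n2 second group's.
#' @return A [PairwiseComparison-class].
#' @examples
#' welchFromSummary(75.63, 23.59, 7, 106.33, 15.12, 7)
#' @export
welchFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    .invalidArg("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0)
    .invalidArg("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(new("PairwiseComparison", tStatistic = 0, df = n1 + n2 - 2,
                 pValue = 1, category = "NS", degenerate = TRUE))
    return(new("PairwiseComparison",
               tStatistic = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2,
               pValue = 0, category = "p<0.001", degenerate = TRUE))
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tStat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tStat), df)
  new("PairwiseComparison", tStatistic = tStat, df = df, pValue = p,
      category = .pCategory(p), degenerate = FALSE)
}

#' Welch t-test between two measurement groups
#'
#' Equivalent to [welchFromSummary()] applied to the two groups' summaries.
#'
#' @param a,b [GroupMeasurements-class] objects, each with n >= 2.
#' @return A [PairwiseComparison-class].
#' @export
welchTest <- function(a, b) {
  sa <- summarizeGroup(a)
  sb <- summarizeGroup(b)
  welchFromSummary(sa@mean, sa@sd, sa@n, sb@mean, sb@sd, sb@n)
}

#' Pairwise Welch comparison matrix
#'
#' Tests every unordered pair of groups and arranges the significance
#' categories in a symmetric matrix with `"NS"` on the diagonal. No
#' multiple-testing correction is applied by default; `adjust` enables
#' Bonferroni or Holm adjustment of the p-values before categorisation.
#'
#' @param groups list of [GroupMeasurements-class] with unique labels
#'   (>= 2 groups).
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A [ComparisonMatrix-class].
#' @export
comparisonMatrix <- function(groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2)
    .invalidArg("a comparison matrix needs at least 2 groups")
  if (!all(vapply(groups, is, logical(1), class2 = "GroupMeasurements")))
    .invalidArg("'groups' must be a list of GroupMeasurements")
  labels <- vapply(groups, groupLabel, character(1))
  if (anyDuplicated(labels))
    .invalidArg("group labels must be unique")
  k <- length(groups)
  pm <- matrix(1, k, k, dimnames = list(labels, labels))
  pairs <- utils::combn(k, 2)
  pvals <- apply(pairs, 2, function(ij) {
    pValue(welchTest(groups[[ij[1]]], groups[[ij[2]]]))
  })
  if (adjust != "none") pvals <- stats::p.adjust(pvals, method = adjust)
  cm <- matrix("NS", k, k, dimnames = list(labels, labels))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pm[i1, i2] <- pm[i2, i1] <- pvals[j]
    cm[i1, i2] <- cm[i2, i1] <- .pCategory(pvals[j])
  }
  new("ComparisonMatrix", labels = labels, categories = cm, pValues = pm)
}
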