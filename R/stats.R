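#' Two-sided Mann-Whitney U test
#'
#' Nonparametric comparison of two samples, the test used for the imaging
#' metrics (area fraction, Aggregation Index) and the per-peak MALDI
#' intensities. In `auto` mode the exact null distribution is used when
#' `n_x + n_y <= 20` and there are no ties; otherwise the normal
#' approximation with midrank tie correction and continuity correction.
#' The reported U statistic counts pairs won by `x`. Two-sided exact p is
#' twice the smaller tail, capped at 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`. Exact mode
#'   with ties falls back to the approximation (with a warning from the
#'   underlying machinery suppressed into the method tag).
#' @return one-row data.frame (`GroupComparison`): `metric`, `group_a`,
#'   `group_b`, `statistic` (U for x), `p_value`, `method`
#'   (`"exact"`/`"normal-approx"`), `n_a`, `n_b`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  hasTies <- anyDuplicated(c(x, y)) > 0L
  useExact <- switch(mode,
    auto = (length(x) + length(y) <= 20L) && !hasTies,
    exact = !hasTies,
    approx = FALSE)
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = useExact,
    correct = TRUE))
  data.frame(metric = NA_character_, group_a = "x", group_b = "y",
             statistic = unname(res$statistic),
             p_value = res$p.value,
             method = if (useExact) "exact" else "normal-approx",
             n_a = length(x), n_b = length(y),
             stringsAsFactors = FALSE)
}

#' Two-sample t-test kernel
#'
#' Shared kernel behind [compareRatios()]. Student's pooled-variance
#' variant by default; Welch by flag. Two-sided.
#'
#' @param x,y numeric samples, each n >= 2 with finite variance.
#' @param variant `"student"` (default) or `"welch"`.
#' @return one-row `GroupComparison` data.frame; `statistic` is t
#'   (positive when `mean(x) > mean(y)`).
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  res <- stats::t.test(x, y, var.equal = (variant == "student"),
                       alternative = "two.sided")
  data.frame(metric = NA_character_, group_a = "x", group_b = "y",
             statistic = unname(res$statistic),
             p_value = res$p.value,
             method = paste0("t-", variant),
             n_a = length(x), n_b = length(y),
             stringsAsFactors = FALSE)
}

#' Summarize differential-expression counts
#'
#' Printed-table arithmetic for differentially expressed gene counts: the
#' total and the integer percentages of up- and downregulated genes,
#' rounded half-up (so a 57.15%/42.85% split prints as 57/43).
#'
#' @param nUp,nDown nonnegative gene counts, not both zero.
#' @param name comparison label.
#' @return one-row data.frame: `name`, `n_up`, `n_down`, `total`,
#'   `pct_up`, `pct_down`.
#' @examples
#' summarizeDegCounts(791, 593)  # 1384 total, 57% up, 43% down
#' summarizeDegCounts(675, 391)  # 1066 total, 63% up, 37% down
#' @export
summarizeDegCounts <- function(nUp, nDown, name = "comparison") {
  stopifnot(nUp >= 0, nDown >= 0)
  if (nUp + nDown == 0) stop("no differentially expressed genes")
  total <- nUp + nDown
  data.frame(name = name, n_up = nUp, n_down = nDown, total = total,
             pct_up = halfUp(100 * nUp / total),
             pct_down = halfUp(100 * nDown / total),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment of a comparison table
#'
#' Optional helper: the analyses report raw per-comparison p-values by
#' default (matching the imaging figures); call this to append an FDR
#' column when many peaks or pairs are tested.
#'
#' @param comparisons a data.frame with a `p_value` column.
#' @return the same data.frame with a `p_adj` (BH) column appended.
#' @export
adjustComparisons <- function(comparisons) {
  stopifnot("p_value" %in% colnames(comparisons))
  comparisons$p_adj <- stats::p.adjust(comparisons$p_value, method = "BH")
  comparisons
}
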