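#' Per-cell JC-1 red/green fluorescence ratios
#'
#' JC-1 accumulates and dimerizes in polarized mitochondria (red
#' J-aggregates); depolarization leaves the dye as diffuse green monomers,
#' so the per-cell mean red / mean green intensity ratio drops with
#' mitochondrial dysfunction. Optionally subtracts a per-channel
#' background estimated as the median intensity of unlabeled pixels.
#' Cells whose (background-corrected) mean green is not positive are
#' flagged and get `NA` ratios rather than infinities.
#'
#' @param red,green numeric matrices of the two channels (same shape).
#' @param mask integer label matrix aligned to the images.
#' @param bgSubtract subtract the median of unlabeled pixels per channel
#'   (default `FALSE`; off because the upstream protocol does not mention
#'   background correction).
#' @return data.frame with `cell_id`, `mean_red`, `mean_green`, `ratio`,
#'   `flag`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' g <- matrix(1, 8, 8); r <- 2 * g
#' perCellRatio(r, g, m)$ratio  # 2
#' @seealso [compareRatios()], [simulateJc1Pair()]
#' @export
perCellRatio <- function(red, green, mask, bgSubtract = FALSE) {
  stopifnot(is.matrix(red), is.matrix(green),
            identical(dim(red), dim(green)), identical(dim(red), dim(mask)))
  ids <- sort(unique(mask[mask > 0L]))
  if (length(ids) == 0L) stop("mask contains no labeled cells")
  bgR <- bgG <- 0
  if (bgSubtract) {
    outside <- mask == 0L
    if (any(outside)) {
      bgR <- stats::median(red[outside])
      bgG <- stats::median(green[outside])
    }
  }
  recs <- lapply(ids, function(k) {
    inCell <- mask == k
    if (!any(inCell)) stop("empty cell label ", k)
    mr <- mean(red[inCell]) - bgR
    mg <- mean(green[inCell]) - bgG
    if (mg <= 0)
      data.frame(cell_id = k, mean_red = mr, mean_green = mg,
                 ratio = NA_real_, flag = "nonpositive_green",
                 stringsAsFactors = FALSE)
    else
      data.frame(cell_id = k, mean_red = mr, mean_green = mg,
                 ratio = mr / mg, flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Compare red/green ratios between two groups by t-test
#'
#' Two-sided two-sample t-test on per-cell JC-1 ratios. The default is the
#' classical pooled-variance (Student) variant; Welch's unequal-variance
#' form is available by flag.
#'
#' @param x,y numeric vectors of per-cell ratios (each n >= 2).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return one-row data.frame (a `GroupComparison`): `metric`, `group_a`,
#'   `group_b`, `statistic` (t), `p_value` (two-sided), `method`, `n_a`,
#'   `n_b`.
#' @examples
#' compareRatios(c(1, 2, 3), c(4, 5, 6))
#' @export
compareRatios <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  cmp <- twoSampleT(x, y, variant)
  cmp$metric <- "jc1_ratio"
  cmp
}
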