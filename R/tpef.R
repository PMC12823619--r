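#' Remove isolated 1-pixel outliers by median filtering
#'
#' Corrects the extreme pixel values left by cosmic rays (bright) and
#' detector dropouts (dark). A pixel is flagged when it is a strict
#' extremum of its `window x window` neighborhood — strictly above every
#' neighbor or strictly below — *and* its gap to the nearest neighbor
#' value exceeds `madFactor` times the scaled MAD of the neighborhood
#' (floored by the absolute `minDeviation`). The gap condition is what
#' makes the detection specific to *1-pixel* events: a sharp but smooth
#' intensity peak always has a near neighbor on its ridge, while a cosmic
#' ray stands clear of all eight neighbors. Flagged pixels are replaced by
#' the neighborhood median; passes repeat until no pixel meets the
#' criterion (almost always 1-2 passes), which makes the operation
#' idempotent by construction. Border pixels are handled by edge
#' replication and can never be strict extrema.
#'
#' @param x numeric matrix or [MultiChannelImage-class] (every channel is
#'   filtered).
#' @param window odd neighborhood size >= 3 (default 3).
#' @param madFactor gap threshold in scaled-MAD units (default 5).
#' @param minDeviation absolute floor (a.u.) on the gap (default 0.05,
#'   well below the 0.25 a.u. signal threshold but above typical detector
#'   noise excursions); prevents flat noise-free regions (MAD 0) from
#'   flagging negligible fluctuations.
#' @param maxPasses safety cap on the fixed-point iteration (default 8).
#' @return object of the same type as `x`; for a matrix, the result
#'   carries attributes `flagged` (the (row, col) indices replaced, over
#'   all passes) and `passes`.
#' @examples
#' m <- matrix(1, 8, 8); m[4, 5] <- 100
#' removeOutliers(m)[4, 5]
#' @seealso [deskewSerpentine()], [runTpefPipeline()]
#' @export
setGeneric("removeOutliers",
  function(x, window = 3L, madFactor = 5, minDeviation = 0.05,
           maxPasses = 8L) standardGeneric("removeOutliers"))

#' @rdname removeOutliers
#' @export
setMethod("removeOutliers", "matrix",
  function(x, window = 3L, madFactor = 5, minDeviation = 0.05,
           maxPasses = 8L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  centerCol <- ((window - 1L) %/% 2L) * window + (window - 1L) %/% 2L + 1L
  out <- x
  flaggedAll <- matrix(FALSE, nrow(x), ncol(x))
  passes <- 0L
  repeat {
    nb <- neighborhoodStack(out, window)
    center <- nb[, centerCol]
    othersDf <- as.data.frame(nb[, -centerCol, drop = FALSE])
    nbMax <- do.call(pmax, othersDf)
    nbMin <- do.call(pmin, othersDf)
    gap <- pmax(center - nbMax, nbMin - center)  # > 0 iff strict extremum
    med <- rowMedianK(nb)
    mad <- 1.4826 * rowMedianK(abs(nb - med))
    flag <- gap > pmax(madFactor * mad, minDeviation)
    if (!any(flag) || passes >= maxPasses) break
    passes <- passes + 1L
    out[flag] <- med[flag]
    flaggedAll <- flaggedAll | matrix(flag, nrow(x), ncol(x))
  }
  if (passes >= maxPasses && any(flag))
    warning("outlier removal did not reach a fixed point in ",
            maxPasses, " passes")
  attr(out, "flagged") <- which(flaggedAll, arr.ind = TRUE)
  attr(out, "passes") <- passes
  out
})

#' @rdname removeOutliers
#' @export
setMethod("removeOutliers", "MultiChannelImage",
  function(x, window = 3L, madFactor = 5, minDeviation = 0.05,
           maxPasses = 8L) {
    ch <- lapply(x@channels, function(m) {
      m2 <- removeOutliers(m, window, madFactor, minDeviation, maxPasses)
      attributes(m2)[c("flagged", "passes")] <- NULL
      m2
    })
    MultiChannelImage(ch, roles = x@roles)
  })

#' Correct serpentine raster distortion by circular row shifts
#'
#' Raster scanning with a serpentine (bidirectional) stage motion shifts
#' alternate lines sideways. The correction estimates the single integer
#' shift `s` in `[-maxShift, maxShift]` that maximizes the mean Pearson
#' correlation between each even row (rows 2, 4, ... ) circularly shifted
#' by `s` and the average of its adjacent odd rows, then applies that shift
#' to the even rows. Ties are broken toward smaller `|s|`, then toward
#' negative `s`. A constant (degenerate) image yields shift 0 with a
#' `degenerate` flag.
#'
#' @param x numeric matrix or [MultiChannelImage-class]. For a
#'   multi-channel image the shift is estimated on the `tpef` channel (or
#'   the first channel) and applied to all channels.
#' @param maxShift maximum |shift| searched; must be < width/4.
#' @return list with `image` (same type as `x`), `shift` (the integer
#'   applied to even rows) and `degenerate` (logical).
#' @examples
#' f <- outer(sin(seq(0, 3, length = 64)), cos(seq(0, 3, length = 64)))
#' g <- f; g[seq(2, 64, 2), ] <- t(apply(f[seq(2, 64, 2), ], 1,
#'   function(v) c(v[62:64], v[1:61])))  # inject +3 shift
#' deskewSerpentine(g)$shift
#' @export
setGeneric("deskewSerpentine",
  function(x, maxShift = 5L) standardGeneric("deskewSerpentine"))

#' @rdname deskewSerpentine
#' @export
setMethod("deskewSerpentine", "matrix", function(x, maxShift = 5L) {
  maxShift <- as.integer(maxShift)
  if (maxShift >= ncol(x) / 4) stop("maxShift must be < width/4")
  H <- nrow(x)
  even <- seq(2L, H, by = 2L)
  refs <- lapply(even, function(r) {
    nbr <- c(r - 1L, r + 1L)
    nbr <- nbr[nbr >= 1L & nbr <= H]
    colMeans(x[nbr, , drop = FALSE])
  })
  shifts <- seq.int(-maxShift, maxShift)
  score <- vapply(shifts, function(s) {
    cc <- mapply(function(r, ref) {
      v <- rotateVec(x[r, ], s)
      if (stats::sd(v) == 0 || stats::sd(ref) == 0) NA_real_
      else stats::cor(v, ref)
    }, even, refs)
    if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(score))) {
    warning("degenerate image: serpentine shift set to 0")
    return(list(image = x, shift = 0L, degenerate = TRUE))
  }
  best <- which(score >= max(score, na.rm = TRUE) - 1e-12)
  cand <- shifts[best]
  cand <- cand[order(abs(cand), cand)]   # min |s| first, then negative
  s <- cand[1L]
  list(image = rotateRows(x, even, s), shift = as.integer(s),
       degenerate = FALSE)
})

#' @rdname deskewSerpentine
#' @export
setMethod("deskewSerpentine", "MultiChannelImage",
  function(x, maxShift = 5L) {
    role <- if ("tpef" %in% x@roles) "tpef" else 1L
    est <- deskewSerpentine(channelMatrix(x, role), maxShift)
    even <- seq(2L, nrow(channelMatrix(x, 1L)), by = 2L)
    ch <- lapply(x@channels, rotateRows, rows = even, s = est$shift)
    list(image = MultiChannelImage(ch, roles = x@roles),
         shift = est$shift, degenerate = est$degenerate)
  })

#' Threshold the endogenous fluorescence signal
#'
#' Applies the absolute intensity threshold (default 0.25 a.u.) that
#' separates endogenous TPEF signal from diffuse background. A pixel
#' belongs to the signal mask iff its value is `>= thr` *and* it lies
#' inside a labeled cell. The threshold is absolute, so images must
#' already be on the instrument's a.u. scale (divide by a calibration
#' factor first if not); no automatic normalization is applied.
#'
#' @param img numeric matrix or [MultiChannelImage-class] (`tpef` channel
#'   used).
#' @param mask integer label matrix (0 = background, k = cell k).
#' @param thr absolute threshold in a.u., > 0 (default 0.25).
#' @return logical matrix of above-threshold in-cell pixels.
#' @export
thresholdSignal <- function(img, mask, thr = 0.25) {
  if (is(img, "MultiChannelImage"))
    img <- channelMatrix(img, if ("tpef" %in% channelRoles(img)) "tpef" else 1L)
  stopifnot(is.matrix(img), identical(dim(img), dim(mask)), thr > 0)
  img >= thr & mask > 0L
}

#' Maximum TPEF signal of a cell (top-decile mean)
#'
#' The "maximum" TPEF value is defined robustly as the mean of the top 10%
#' highest pixel values of the cell (count `ceiling(0.10 * n)`), which
#' together with outlier removal avoids spurious single-pixel values while
#' scaling with the peak fluorophore density.
#'
#' @param values numeric vector of in-cell pixel intensities (>= 10
#'   pixels).
#' @param topFraction fraction of highest pixels averaged (default 0.10).
#' @return scalar a.u. value.
#' @examples
#' maxTpef(1:10)  # top 10% of 10 pixels = {10}
#' @export
maxTpef <- function(values, topFraction = 0.10) {
  n <- length(values)
  if (n == 0L) stop("empty cell mask")
  if (n < 10L) stop("cell has fewer than 10 pixels")
  m <- ceiling(topFraction * n)
  mean(sort(values, decreasing = TRUE)[seq_len(m)])
}

#' Mitochondrial Aggregation Index
#'
#' `AI = maxTpef / areaFractionPct`, with the area fraction expressed on
#' the 0-100 percent scale: the maximum coenzyme density normalized by how
#' widely the signal is spread over the cell. Dispersed (senescent-like)
#' cells have a lower AI than cells with tight mitochondrial aggregates.
#'
#' @param maxTpef top-decile mean TPEF (a.u.).
#' @param areaFractionPct percent of cell area above threshold, in
#'   \[0, 100\].
#' @return the index (a.u. per percent), or `NA` when the fraction is 0
#'   (undefined, reported as missing rather than zero).
#' @examples
#' aggregationIndex(1.0, 50)   # 0.02
#' aggregationIndex(0.8, 100)  # 0.008
#' @export
aggregationIndex <- function(maxTpef, areaFractionPct) {
  stopifnot(areaFractionPct >= 0, areaFractionPct <= 100)
  ifelse(areaFractionPct > 0, maxTpef / areaFractionPct, NA_real_)
}

#' Per-cell TPEF metrics
#'
#' Computes, for every labeled cell, the top-decile maximum TPEF, the
#' above-threshold TPEF area, the cell area, the TPEF area fraction (%),
#' and the Aggregation Index. Cells with no above-threshold pixel or fewer
#' than `minCellSize` pixels are flagged and their AI reported as `NA`.
#'
#' @param img numeric matrix or [MultiChannelImage-class] (already
#'   outlier-filtered and deskewed).
#' @param mask integer label matrix aligned to `img`.
#' @param thr absolute threshold (a.u.), default 0.25.
#' @param topFraction top-pixel fraction for [maxTpef()], default 0.10.
#' @param minCellSize minimum pixels per cell (default 10).
#' @return data.frame with columns `cell_id`, `max_tpef`, `area_tpef`,
#'   `area_cell`, `area_fraction_pct`, `aggregation_index`, `flag`.
#' @export
tpefRecords <- function(img, mask, thr = 0.25, topFraction = 0.10,
                        minCellSize = 10L) {
  if (is(img, "MultiChannelImage"))
    img <- channelMatrix(img, if ("tpef" %in% channelRoles(img)) "tpef" else 1L)
  stopifnot(identical(dim(img), dim(mask)))
  sig <- thresholdSignal(img, mask, thr)
  ids <- sort(unique(mask[mask > 0L]))
  recs <- lapply(ids, function(k) {
    inCell <- mask == k
    areaCell <- sum(inCell)
    areaTpef <- sum(sig & inCell)
    flag <- ""
    mt <- NA_real_; frac <- NA_real_; ai <- NA_real_
    if (areaCell < minCellSize) {
      flag <- "too_small"
    } else {
      mt <- maxTpef(img[inCell], topFraction)
      frac <- 100 * areaTpef / areaCell
      if (areaTpef == 0L) {
        flag <- "empty_tpef"
      } else {
        ai <- aggregationIndex(mt, frac)
      }
    }
    data.frame(cell_id = k, max_tpef = mt, area_tpef = areaTpef,
               area_cell = areaCell, area_fraction_pct = frac,
               aggregation_index = ai, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Run the full TPEF pipeline over grouped images
#'
#' Fixed processing order per field of view: outlier removal, serpentine
#' deskew, absolute thresholding, per-cell metrics — then two-sided
#' Mann-Whitney U comparisons of the Aggregation Index and of the TPEF
#' area fraction between every pair of groups.
#'
#' @param images list of numeric matrices or [MultiChannelImage-class]
#'   objects, one per field of view.
#' @param masks list of integer label matrices, parallel to `images`.
#' @param groups character vector of group labels, one per image.
#' @param thr absolute threshold (a.u.), default 0.25.
#' @param window,madFactor outlier-filter parameters, see
#'   [removeOutliers()].
#' @param maxShift deskew search range, see [deskewSerpentine()].
#' @param topFraction top-pixel fraction for [maxTpef()].
#' @return list with `records` (per-cell data.frame including `group` and
#'   `image`), `comparisons` (per group pair and metric: U statistic,
#'   two-sided p, method, group sizes) and `log` (the ordered processing
#'   steps actually run).
#' @export
runTpefPipeline <- function(images, masks, groups, thr = 0.25,
                            window = 3L, madFactor = 5, maxShift = 5L,
                            topFraction = 0.10) {
  stopifnot(length(images) == length(masks),
            length(images) == length(groups))
  if (length(unique(groups)) < 2L) stop("need >= 2 groups")
  log <- character(0)
  records <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is(img, "MultiChannelImage"))
      img <- channelMatrix(img,
        if ("tpef" %in% channelRoles(img)) "tpef" else 1L)
    img <- removeOutliers(img, window, madFactor)
    img <- deskewSerpentine(img, maxShift)$image
    rec <- tpefRecords(img, masks[[i]], thr, topFraction)
    rec$group <- groups[i]
    rec$image <- i
    rec$cell_id <- sprintf("img%d_cell%d", i, rec$cell_id)
    records[[i]] <- rec
  }
  log <- c("remove_outliers", "deskew_serpentine", "threshold_signal",
           "per_cell_metrics", "group_comparison")
  records <- do.call(rbind, records)
  glev <- unique(groups)
  comparisons <- list()
  for (a in seq_along(glev)) for (b in seq_along(glev)) {
    if (a >= b) next
    for (metric in c("aggregation_index", "area_fraction_pct")) {
      xa <- records[records$group == glev[a] & records$flag == "", metric]
      xb <- records[records$group == glev[b] & records$flag == "", metric]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 3L || length(xb) < 3L) {
        warning("comparison skipped for metric ", metric, ": group with ",
                "fewer than 3 valid cells")
        next
      }
      cmp <- mannWhitneyU(xa, xb)
      cmp$metric <- metric
      cmp$group_a <- glev[a]; cmp$group_b <- glev[b]
      comparisons[[length(comparisons) + 1L]] <- cmp
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else NULL
  list(records = records, comparisons = comparisons, log = log)
}

#' Convenience cell segmenter from a transmission channel
#'
#' Optional helper for data without label masks: box-smooths the
#' transmission channel, thresholds it by Otsu's method and labels
#' 4-connected components, discarding components below `minSize` pixels.
#' The quantitative metrics never depend on it — supplying curated label
#' masks is always preferred.
#'
#' @param img numeric matrix (transmission or similar contrast channel).
#' @param minSize minimum component size in pixels (default 200).
#' @param smooth half-width of the box smoothing (default 2; 0 disables).
#' @return integer label matrix (0 = background, 1..n = cells).
#' @export
segmentCells <- function(img, minSize = 200L, smooth = 2L) {
  stopifnot(is.matrix(img))
  s <- img
  if (smooth > 0L) {
    k <- 2L * smooth + 1L
    s <- t(apply(s, 1L, function(v)
      stats::filter(v, rep(1 / k, k), sides = 2L)))
    s <- apply(s, 2L, function(v)
      stats::filter(v, rep(1 / k, k), sides = 2L))
    s[is.na(s)] <- 0
  }
  thr <- otsuThreshold(s)
  fg <- s > thr
  lab <- labelComponents(fg)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minSize)
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# Otsu's between-class-variance maximizing threshold over 256 bins.
otsuThreshold <- function(x) {
  v <- as.vector(x)
  br <- seq(min(v), max(v), length.out = 257L)
  if (br[1L] == br[257L]) return(br[1L])
  h <- hist(v, breaks = br, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (br[-257L] + br[-1L]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[256L]
  bcv <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# 4-connected component labeling by iterative flood fill.
labelComponents <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nextLab <- 0L
  idx <- which(fg)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    lab[start] <- nextLab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% H) + 1L
      cl <- ((cur - 1L) %/% H) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- cl + d[2L]
        if (rr >= 1L && rr <= H && cc >= 1L && cc <= W) {
          j <- (cc - 1L) * H + rr
          if (fg[j] && lab[j] == 0L) {
            lab[j] <- nextLab
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  lab
}
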