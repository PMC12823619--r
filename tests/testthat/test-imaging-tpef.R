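test_that("removeOutliers fixes a lone spike and leaves clean images alone", {
  m <- matrix(1, 12, 12)
  m[5, 7] <- 100
  out <- removeOutliers(m)
  expect_equal(out[5, 7], 1)
  expect_equal(unclass(out)[-(6 * 12 + 5)], m[-(6 * 12 + 5)])
  expect_equal(nrow(attr(out, "flagged")), 1L)
  # identity on an image with no qualifying pixel
  clean <- outer(seq(0, 1, length = 12), seq(0, 1, length = 12))
  out2 <- removeOutliers(clean)
  expect_equal(nrow(attr(out2, "flagged")), 0L)
  expect_equal(unclass(out2), clean, ignore_attr = TRUE)
  expect_error(removeOutliers(m, window = 4), "odd")
})

test_that("injected extrema on a structured field are flagged and median-replaced", {
  img <- smoothField(n = 64, seed = 42)$img
  pos <- cbind(c(5, 15, 25, 33), c(8, 30, 12, 36))
  vals <- c(6, -4, 8, -5)
  for (i in 1:4) img[pos[i, 1], pos[i, 2]] <- vals[i]
  out <- removeOutliers(img)
  fl <- attr(out, "flagged")
  expect_setequal(posKey(fl), posKey(pos))
  for (i in 1:4)
    expect_equal(out[pos[i, 1], pos[i, 2]],
                 bruteMedian3(img, pos[i, 1], pos[i, 2]))
})

test_that("removeOutliers is idempotent on its own output", {
  sim <- simulateTpefImage(tpefSimConfig(imageSize = c(128, 128),
                                         nCells = 6L, seed = 17))
  f1 <- removeOutliers(channelMatrix(sim$image))
  attributes(f1)[c("flagged", "passes")] <- NULL
  f2 <- removeOutliers(f1)
  attributes(f2)[c("flagged", "passes")] <- NULL
  expect_identical(f1, f2)
})

test_that("deskew recovers an injected shift exactly and restores the field", {
  sf <- smoothField()
  even <- seq(2, nrow(sf$img), by = 2)
  shifted <- senometrix:::rotateRows(sf$img, even, 3L)
  est <- deskewSerpentine(shifted, maxShift = 5)
  expect_equal(est$shift, -3L)
  expect_equal(est$image, sf$img)
  # zero-shift input is returned unchanged
  est0 <- deskewSerpentine(sf$img, maxShift = 5)
  expect_equal(est0$shift, 0L)
  expect_identical(est0$image, sf$img)
})

test_that("deskew is exactly invertible and flags degenerate input", {
  sf <- smoothField(seed = 23)
  even <- seq(2, nrow(sf$img), by = 2)
  shifted <- senometrix:::rotateRows(sf$img, even, -4L)
  est <- deskewSerpentine(shifted, maxShift = 5)
  reinjected <- senometrix:::rotateRows(est$image, even, -est$shift)
  expect_identical(reinjected, shifted)
  expect_warning(res <- deskewSerpentine(matrix(1, 32, 32)), "degenerate")
  expect_equal(res$shift, 0L)
  expect_true(res$degenerate)
})

test_that("correlation ties break toward the smaller magnitude, then negative", {
  # period-2 columns: every even shift aligns equally -> 0 must win
  per <- matrix(rep(c(0, 1), 16), 16, 32, byrow = TRUE)
  expect_equal(deskewSerpentine(per, maxShift = 4)$shift, 0L)
  # even rows offset by 1 against period-2 pattern: -1 and +1 tie -> -1
  per2 <- per
  even <- seq(2, 16, by = 2)
  per2[even, ] <- senometrix:::rotateRows(per, even, 1L)[even, ]
  expect_equal(deskewSerpentine(per2, maxShift = 4)$shift, -1L)
})

test_that("thresholdSignal applies the absolute 0.25 a.u. cut inside cells", {
  mask <- matrix(0L, 10, 10)
  mask[3:8, 3:8] <- 1L
  imgHi <- matrix(0.30, 10, 10)
  expect_equal(sum(thresholdSignal(imgHi, mask)), sum(mask == 1L))
  imgLo <- matrix(0.10, 10, 10)
  expect_equal(sum(thresholdSignal(imgLo, mask)), 0L)
  rec <- tpefRecords(imgLo, mask)
  expect_equal(rec$flag, "empty_tpef")
  expect_true(is.na(rec$aggregation_index))
  # half above, half below -> fraction 50% by brute-force pixel counting
  imgHalf <- imgHi
  imgHalf[, 1:5] <- 0.20
  rec2 <- tpefRecords(imgHalf, mask)
  bruteFrac <- 100 * sum(imgHalf >= 0.25 & mask == 1L) / sum(mask == 1L)
  expect_equal(rec2$area_fraction_pct, bruteFrac)
  expect_equal(rec2$area_fraction_pct, 50)
})

test_that("maxTpef is the mean of the top decile (ceiling count)", {
  expect_equal(maxTpef(1:10), 10)
  expect_equal(maxTpef(rep(3.5, 40)), 3.5)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    v <- rnorm(n)
    oracle <- mean(sort(v, decreasing = TRUE)[seq_len(ceiling(0.1 * n))])
    expect_equal(maxTpef(v), oracle)
  }
  expect_error(maxTpef(numeric(0)), "empty")
  expect_error(maxTpef(1:5), "fewer than 10")
})

test_that("aggregationIndex arithmetic and degenerate handling", {
  expect_equal(aggregationIndex(1.0, 50), 0.02)
  expect_equal(aggregationIndex(0.8, 100), 0.008)
  expect_true(is.na(aggregationIndex(1.0, 0)))
})

test_that("AI is invariant to relabeling and translation, not to rescaling", {
  sf <- smoothField(seed = 31)
  rec <- tpefRecords(sf$img, sf$mask)
  # relabel cells (permute labels)
  perm <- c(3L, 1L, 2L)
  mask2 <- sf$mask
  mask2[sf$mask > 0] <- perm[sf$mask[sf$mask > 0]]
  rec2 <- tpefRecords(sf$img, mask2)
  expect_equal(sort(rec$aggregation_index), sort(rec2$aggregation_index))
  # translate image and mask together by (2, 3) — cells stay intact
  H <- nrow(sf$img); W <- ncol(sf$img)
  tr <- function(m, fill) {
    out <- matrix(fill, H, W)
    out[3:H, 4:W] <- m[1:(H - 2), 1:(W - 3)]
    out
  }
  rec3 <- tpefRecords(tr(sf$img, 0), tr(sf$mask, 0L))
  expect_equal(rec3$aggregation_index, rec$aggregation_index)
  # doubling intensities changes both ingredients (absolute threshold)
  rec4 <- tpefRecords(2 * sf$img, sf$mask)
  expect_false(isTRUE(all.equal(rec4$max_tpef, rec$max_tpef)))
  expect_false(isTRUE(all.equal(rec4$area_fraction_pct,
                                rec$area_fraction_pct)))
})

test_that("aggregated cells score a higher AI than dispersed cells", {
  mkimg <- function(agg, seed) simulateTpefImage(tpefSimConfig(
    imageSize = c(128, 128), nCells = 8L, aggregation = agg,
    backgroundSd = 0, nOutliers = 0L, serpentineShift = 0L, seed = seed))
  hi <- mkimg(1, 61); lo <- mkimg(0, 61)
  recHi <- tpefRecords(channelMatrix(hi$image), hi$mask)
  recLo <- tpefRecords(channelMatrix(lo$image), lo$mask)
  expect_gt(median(recHi$aggregation_index, na.rm = TRUE),
            median(recLo$aggregation_index, na.rm = TRUE))
})

test_that("the pipeline compares groups in the documented order", {
  simA <- simulateTpefImage(tpefSimConfig(imageSize = c(128, 128),
                                          nCells = 8L, aggregation = 1,
                                          seed = 71))
  simB <- simulateTpefImage(tpefSimConfig(imageSize = c(128, 128),
                                          nCells = 8L, aggregation = 0.2,
                                          seed = 72))
  res <- runTpefPipeline(
    list(channelMatrix(simA$image), channelMatrix(simB$image)),
    list(simA$mask, simB$mask), c("aggregated", "dispersed"))
  expect_identical(res$log, c("remove_outliers", "deskew_serpentine",
                              "threshold_signal", "per_cell_metrics",
                              "group_comparison"))
  ai <- res$comparisons[res$comparisons$metric == "aggregation_index", ]
  expect_lt(ai$p_value, 0.01)
  # duplicated groups compare as identical: p = 1
  res2 <- runTpefPipeline(
    list(channelMatrix(simA$image), channelMatrix(simA$image)),
    list(simA$mask, simA$mask), c("g1", "g2"))
  expect_equal(res2$comparisons$p_value, c(1, 1))
  expect_error(runTpefPipeline(list(channelMatrix(simA$image)),
                               list(simA$mask), "only"), "2 groups")
})

test_that("the convenience segmenter labels the simulated cells", {
  # use a dispersed noiseless field as a transmission-like contrast
  sim <- simulateTpefImage(tpefSimConfig(imageSize = c(96, 96), nCells = 3L,
                                         aggregation = 0, backgroundSd = 0,
                                         nOutliers = 0L, serpentineShift = 0L,
                                         seed = 41))
  lab <- segmentCells(channelMatrix(sim$image), minSize = 100L)
  expect_equal(max(lab), 3L)
})
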