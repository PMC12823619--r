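#' Configuration for the synthetic TPEF image generator
#'
#' Defines one simulated field of view of autofluorescent cells. The
#' `aggregation` parameter interpolates between a fully dispersed
#' distribution of the fluorophore over the cell (0) and tight punctate
#' spots (1) at *fixed total injected intensity per cell*, emulating
#' mitochondrial coenzyme aggregation versus cytosolic dispersal. The
#' generator also reproduces the acquisition artifacts the preprocessing
#' recipe targets: 1-pixel cosmic-ray extrema and the serpentine row shift
#' of a raster-scanning stage.
#'
#' @param imageSize integer (rows, cols) in pixels.
#' @param nCells number of non-overlapping elliptical cells to place.
#' @param spotsPerCell punctate spots per cell.
#' @param spotSigma Gaussian spot width (pixels), > 0.
#' @param aggregation mixing weight in \[0, 1\]: 1 = all intensity in spots,
#'   0 = uniform over the cell.
#' @param peakAmplitude nominal spot peak amplitude (a.u.).
#' @param backgroundSd additive Gaussian detector noise sd (a.u.).
#' @param nOutliers number of injected 1-pixel cosmic-ray outliers.
#' @param serpentineShift circular shift (pixels) applied to rows
#'   2, 4, ... ; must be within +/- width/4.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated config list of class `TpefSimConfig`.
#' @seealso [simulateTpefImage()]
#' @export
tpefSimConfig <- function(imageSize = c(256L, 256L), nCells = 20L,
                          spotsPerCell = 6L, spotSigma = 2,
                          aggregation = 1, peakAmplitude = 1,
                          backgroundSd = 0.02, nOutliers = 5L,
                          serpentineShift = 2L, seed = 1L) {
  cfg <- list(imageSize = as.integer(imageSize), nCells = as.integer(nCells),
              spotsPerCell = as.integer(spotsPerCell), spotSigma = spotSigma,
              aggregation = aggregation, peakAmplitude = peakAmplitude,
              backgroundSd = backgroundSd, nOutliers = as.integer(nOutliers),
              serpentineShift = as.integer(serpentineShift),
              seed = as.integer(seed))
  stopifnot(length(cfg$imageSize) == 2L, all(cfg$imageSize >= 32L),
            cfg$nCells >= 1L, cfg$spotsPerCell >= 1L, cfg$spotSigma > 0,
            cfg$aggregation >= 0, cfg$aggregation <= 1,
            cfg$peakAmplitude > 0, cfg$backgroundSd >= 0, cfg$nOutliers >= 0L)
  if (abs(cfg$serpentineShift) > cfg$imageSize[2L] / 4)
    stop("serpentineShift must be within +/- width/4")
  class(cfg) <- "TpefSimConfig"
  cfg
}

# Place n non-overlapping ellipses with >= 1.5 px clearance; returns the
# integer label mask and a data.frame of cell geometry. Errors if a cell
# cannot be placed after maxTries rejections.
placeEllipses <- function(H, W, n, aRange = c(9, 14), bRange = c(6, 10),
                          margin = 3, maxTries = 400L) {
  mask <- matrix(0L, H, W)
  cells <- vector("list", n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      a <- stats::runif(1, aRange[1L], aRange[2L])
      b <- stats::runif(1, bRange[1L], bRange[2L])
      th <- stats::runif(1, 0, pi)
      r <- max(a, b) + 2
      if (H - r - margin <= r + margin || W - r - margin <= r + margin)
        stop("image too small for requested cell size")
      cy <- stats::runif(1, r + margin, H - r - margin)
      cx <- stats::runif(1, r + margin, W - r - margin)
      rr <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
      cc <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
      dy <- matrix(rr - cy, length(rr), length(cc))
      dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      clear <- (u / (a + 1.5))^2 + (v / (b + 1.5))^2 <= 1
      sub <- mask[rr, cc]
      if (!any(sub[clear] != 0L)) {
        sub[inside] <- k
        mask[rr, cc] <- sub
        cells[[k]] <- data.frame(cell = k, cy = cy, cx = cx,
                                 a = a, b = b, theta = th)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cell ", k, " without overlap after ",
           maxTries, " tries")
  }
  list(mask = mask, cells = do.call(rbind, cells))
}

# Pick positions with pairwise Chebyshev distance >= minSep (greedy over a
# shuffled candidate list). cand is a 2-column (row, col) matrix.
pickSeparated <- function(cand, k, minSep = 3L) {
  if (k == 0L || nrow(cand) == 0L) return(cand[0L, , drop = FALSE])
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  keep <- matrix(0L, 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) == 0L ||
        all(pmax(abs(keep[, 1L] - p[1L]), abs(keep[, 2L] - p[2L])) >= minSep)) {
      keep <- rbind(keep, p)
      if (nrow(keep) == k) break
    }
  }
  keep
}

#' Simulate a TPEF autofluorescence image with known ground truth
#'
#' Builds a noiseless intensity field of `nCells` elliptical cells, each
#' containing a mixture of punctate Gaussian spots (weight `aggregation`)
#' and a uniform dispersed component (weight `1 - aggregation`), rescaled
#' so the total injected intensity per cell equals
#' `spotsPerCell * peakAmplitude * 2 * pi * spotSigma^2` regardless of
#' `aggregation`. Additive Gaussian background noise is then applied,
#' alternate rows are circularly shifted by `serpentineShift` (the raster
#' artifact), and finally `nOutliers` isolated 1-pixel extrema are injected
#' (so outlier removal is exercised *before* deskewing, matching the
#' preprocessing order). Bright outliers can land anywhere; dark (dropout)
#' outliers are only placed where the local 3x3 neighborhood is
#' signal-bearing and locally smooth, because a zero pixel inside an
#' already-dark or steep region is not a well-defined 1-pixel outlier.
#'
#' @param cfg a [tpefSimConfig()].
#' @return list with elements `image` ([MultiChannelImage-class], one
#'   `tpef` channel), `mask` (integer label matrix aligned to the
#'   *deskewed* geometry), and `truth` (spot centers, cell table, outlier
#'   positions/types, applied shift, aggregation).
#' @examples
#' sim <- simulateTpefImage(tpefSimConfig(imageSize = c(96, 96), nCells = 3,
#'                                        nOutliers = 2, seed = 7))
#' sim$image
#' @export
simulateTpefImage <- function(cfg) {
  stopifnot(inherits(cfg, "TpefSimConfig"))
  withSeed(cfg$seed, {
    H <- cfg$imageSize[1L]; W <- cfg$imageSize[2L]
    pl <- placeEllipses(H, W, cfg$nCells)
    mask <- pl$mask
    img <- matrix(0, H, W)
    total <- cfg$spotsPerCell * cfg$peakAmplitude * 2 * pi * cfg$spotSigma^2
    spots <- vector("list", cfg$nCells)
    for (k in seq_len(cfg$nCells)) {
      px <- which(mask == k, arr.ind = TRUE)
      geo <- pl$cells[k, ]
      ang <- stats::runif(cfg$spotsPerCell, 0, 2 * pi)
      rad <- sqrt(stats::runif(cfg$spotsPerCell))
      u <- 0.7 * geo$a * rad * cos(ang)
      v <- 0.7 * geo$b * rad * sin(ang)
      sr <- round(geo$cy + u * cos(geo$theta) - v * sin(geo$theta))
      sc <- round(geo$cx + u * sin(geo$theta) + v * cos(geo$theta))
      d2 <- outer(px[, 1L], sr, "-")^2 + outer(px[, 2L], sc, "-")^2
      spot <- cfg$peakAmplitude *
        rowSums(exp(-d2 / (2 * cfg$spotSigma^2)))
      spot <- spot * (total / sum(spot))          # exact per-cell mass
      unif <- total / nrow(px)
      img[px] <- cfg$aggregation * spot + (1 - cfg$aggregation) * unif
      spots[[k]] <- data.frame(cell = k, row = sr, col = sc)
    }
    if (cfg$backgroundSd > 0)
      img <- pmax(img + matrix(stats::rnorm(H * W, 0, cfg$backgroundSd), H, W), 0)
    evenRows <- seq(2L, H, by = 2L)
    img <- rotateRows(img, evenRows, cfg$serpentineShift)
    outliers <- data.frame(row = integer(0), col = integer(0),
                           type = character(0))
    if (cfg$nOutliers > 0L) {
      nb <- neighborhoodStack(img, 3L)
      nbMin <- do.call(pmin, as.data.frame(nb))
      nbMax <- do.call(pmax, as.data.frame(nb))
      nbMed <- rowMedian9(nb)
      interior <- matrix(FALSE, H, W)
      interior[3:(H - 2L), 3:(W - 2L)] <- TRUE
      darkOk <- interior & matrix(nbMin >= 0.1 * cfg$peakAmplitude &
                                  (nbMax - nbMin) <= 0.2 * nbMed, H, W)
      nDark <- cfg$nOutliers %/% 2L
      darkPos <- pickSeparated(which(darkOk, arr.ind = TRUE), nDark)
      brCand <- which(interior, arr.ind = TRUE)
      if (nrow(darkPos) > 0L)                    # keep bright away from dark
        brCand <- brCand[apply(brCand, 1L, function(p)
          all(pmax(abs(darkPos[, 1L] - p[1L]),
                   abs(darkPos[, 2L] - p[2L])) >= 3L)), , drop = FALSE]
      brPos <- pickSeparated(brCand, cfg$nOutliers - nrow(darkPos))
      if (nrow(darkPos) + nrow(brPos) < cfg$nOutliers)
        stop("could not place ", cfg$nOutliers, " separated outliers")
      bright <- 10 * (max(img) + 1)
      if (nrow(darkPos) > 0L) img[darkPos] <- 0
      if (nrow(brPos) > 0L) img[brPos] <- bright
      outliers <- rbind(
        if (nrow(darkPos) > 0L)
          data.frame(row = darkPos[, 1L], col = darkPos[, 2L], type = "dark"),
        if (nrow(brPos) > 0L)
          data.frame(row = brPos[, 1L], col = brPos[, 2L], type = "bright"))
    }
    list(image = MultiChannelImage(list(tpef = img)),
         mask = mask,
         truth = list(spots = do.call(rbind, spots), cells = pl$cells,
                      outliers = outliers,
                      serpentineShift = cfg$serpentineShift,
                      aggregation = cfg$aggregation))
  })
}

#' Configuration for the synthetic JC-1 red/green image pair generator
#'
#' Emulates the ratiometric readout of the JC-1 mitochondrial
#' membrane-potential dye: polarized cells show a high red/green ratio
#' (red J-aggregates), depolarized cells a low one (green monomers).
#' Per-cell true ratios are drawn from truncated normal distributions.
#'
#' @param nCellsPerGroup cells per group (the study measured 50 cells per
#'   group for two of the three cell lines).
#' @param polarizedRatioMean,depolarizedRatioMean mean red/green ratio of
#'   the two groups (> 0).
#' @param ratioSd ratio standard deviation (>= 0); non-positive draws are
#'   resampled.
#' @param imageSize integer (rows, cols).
#' @param seed integer seed.
#' @return a config list of class `Jc1SimConfig`.
#' @seealso [simulateJc1Pair()]
#' @export
jc1SimConfig <- function(nCellsPerGroup = 50L, polarizedRatioMean = 2.0,
                         depolarizedRatioMean = 0.8, ratioSd = 0.3,
                         imageSize = c(384L, 384L), seed = 1L) {
  cfg <- list(nCellsPerGroup = as.integer(nCellsPerGroup),
              polarizedRatioMean = polarizedRatioMean,
              depolarizedRatioMean = depolarizedRatioMean,
              ratioSd = ratioSd, imageSize = as.integer(imageSize),
              seed = as.integer(seed))
  stopifnot(cfg$nCellsPerGroup >= 1L, cfg$polarizedRatioMean > 0,
            cfg$depolarizedRatioMean > 0, cfg$ratioSd >= 0)
  class(cfg) <- "Jc1SimConfig"
  cfg
}

#' Simulate a JC-1 red/green image pair with known per-cell ratios
#'
#' Places `2 * nCellsPerGroup` cells in one field; each cell is filled with
#' a constant green level (uniform 0.8-1.2 a.u. across cells) and a red
#' level equal to its drawn true ratio times that green level, so the
#' measured per-cell mean(red)/mean(green) equals the true ratio up to
#' floating-point error. Ratios <= 0 are resampled (truncation).
#'
#' @param cfg a [jc1SimConfig()].
#' @return list with `red`, `green` (matrices), `mask` (integer label
#'   matrix) and `truth` data.frame (cell, group, trueRatio).
#' @examples
#' sim <- simulateJc1Pair(jc1SimConfig(nCellsPerGroup = 4,
#'                                     imageSize = c(128, 128), seed = 3))
#' head(sim$truth)
#' @export
simulateJc1Pair <- function(cfg) {
  stopifnot(inherits(cfg, "Jc1SimConfig"))
  withSeed(cfg$seed, {
    n <- cfg$nCellsPerGroup
    H <- cfg$imageSize[1L]; W <- cfg$imageSize[2L]
    pl <- placeEllipses(H, W, 2L * n, aRange = c(7, 11), bRange = c(5, 8))
    drawRatios <- function(mu) {
      r <- stats::rnorm(n, mu, cfg$ratioSd)
      for (i in seq_len(1000L)) {
        bad <- r <= 0
        if (!any(bad)) break
        r[bad] <- stats::rnorm(sum(bad), mu, cfg$ratioSd)
      }
      if (any(r <= 0)) stop("could not draw positive ratios")
      r
    }
    ratios <- c(drawRatios(cfg$polarizedRatioMean),
                drawRatios(cfg$depolarizedRatioMean))
    group <- rep(c("polarized", "depolarized"), each = n)
    red <- matrix(0, H, W); green <- matrix(0, H, W)
    for (k in seq_len(2L * n)) {
      px <- pl$mask == k
      gl <- stats::runif(1, 0.8, 1.2)
      green[px] <- gl
      red[px] <- ratios[k] * gl
    }
    list(red = red, green = green, mask = pl$mask,
         truth = data.frame(cell = seq_len(2L * n), group = group,
                            trueRatio = ratios))
  })
}

#' Default lipid peak table for the spectrum simulator
#'
#' Fourteen negative-ion-mode lipid peaks spanning the three diagnostic m/z
#' regions, including the four annotated diagnostic species: CerP
#' (d16:1/18:0) at m/z 616.47, PG (18:1/18:1) at 773, SM (d18:1/24:1) at
#' 797.67 and PG (18:1/22:6) at 819; the cardiolipin region 1300-1500
#' carries three CL peaks. Base intensities are arbitrary units before
#' group effects and TIC jitter.
#'
#' @return data.frame with columns `mz`, `intensity`, `species`, `class`.
#' @export
defaultPeakTable <- function() {
  data.frame(
    mz = c(616.47, 687.50, 716.52, 747.52, 773.00, 797.67, 819.00,
           835.53, 857.52, 885.56, 909.55, 1350.90, 1400.92, 1448.00),
    intensity = c(40, 55, 70, 50, 65, 60, 45, 60, 45, 80, 40, 30, 35, 25),
    species = c("CerP(d16:1/18:0)", NA, NA, NA, "PG(18:1/18:1)",
                "SM(d18:1/24:1)", "PG(18:1/22:6)", NA, NA, NA, NA,
                NA, NA, NA),
    class = c("CerP", "PE", "PE", "PA", "PG", "SM", "PG",
              "PI", "PI", "PI", "PI", "CL", "CL", "CL"),
    stringsAsFactors = FALSE)
}

#' Default group-effect matrix for the spectrum simulator
#'
#' Multiplicative per-region intensity effects for the three experimental
#' groups, mirroring the qualitative pattern of the lipid findings: both
#' senescence inducers double the cardiolipin region (Region 3), while the
#' phosphatide (Region 1) and PI (Region 2) regions move in opposite
#' directions for the two inducers, giving each group a distinct signature.
#' All effects are at least 1.5-fold in magnitude.
#'
#' @return 3 x 3 numeric matrix, rows `control`, `doxorubicin`,
#'   `radiation`; columns `Region1`..`Region3`.
#' @export
defaultGroupEffects <- function() {
  m <- rbind(control      = c(1.0, 1.0, 1.0),
             doxorubicin  = c(1.5, 0.6, 2.0),
             radiation    = c(0.6, 1.5, 2.0))
  colnames(m) <- c("Region1", "Region2", "Region3")
  m
}

#' Configuration for the synthetic MALDI lipid-spectrum generator
#'
#' Each simulated spectrum is a sum of Gaussian peaks at the peak-table
#' positions, scaled by the group's per-region multiplicative effect, by a
#' per-spectrum TIC jitter factor, and by pointwise multiplicative
#' log-normal noise (mean 1, coefficient of variation `noiseCv`).
#'
#' @param peakTable data.frame with at least `mz` and `intensity`; default
#'   [defaultPeakTable()].
#' @param groupEffects numeric matrix, groups x effect regions; rownames
#'   are the group names. Default [defaultGroupEffects()].
#' @param effectRegions region scheme the effect columns refer to; default
#'   [defaultRegions()]. Peaks outside every region get effect 1.
#' @param mzRange numeric (low, high) in Da.
#' @param mzStep grid step (Da).
#' @param peakWidthFwhm peak full width at half maximum (Da); the default
#'   0.18 matches a resolving power of about 5000 at m/z 885.56.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param ticJitter numeric (low, high) range of the per-spectrum TIC
#'   factor, or a scalar for a fixed factor.
#' @param nSpectraPerGroup spectra per group.
#' @param nReplicates biological replicates per group (the study used 3);
#'   spectra cycle over replicates.
#' @param seed integer seed.
#' @return a config list of class `SpectraSimConfig`.
#' @seealso [simulateSpectra()]
#' @export
spectraSimConfig <- function(peakTable = defaultPeakTable(),
                             groupEffects = defaultGroupEffects(),
                             effectRegions = defaultRegions(),
                             mzRange = c(600, 1500), mzStep = 0.1,
                             peakWidthFwhm = 0.18, noiseCv = 0.1,
                             ticJitter = c(0.8, 1.25),
                             nSpectraPerGroup = 20L, nReplicates = 3L,
                             seed = 1L) {
  if (length(ticJitter) == 1L) ticJitter <- rep(ticJitter, 2L)
  cfg <- list(peakTable = peakTable, groupEffects = as.matrix(groupEffects),
              effectRegions = effectRegions, mzRange = mzRange,
              mzStep = mzStep, peakWidthFwhm = peakWidthFwhm,
              noiseCv = noiseCv, ticJitter = ticJitter,
              nSpectraPerGroup = as.integer(nSpectraPerGroup),
              nReplicates = as.integer(nReplicates), seed = as.integer(seed))
  stopifnot(is.data.frame(peakTable), all(c("mz", "intensity") %in%
            colnames(peakTable)), all(peakTable$intensity >= 0),
            cfg$mzStep > 0, cfg$mzRange[2L] > cfg$mzRange[1L],
            cfg$peakWidthFwhm > 0, cfg$noiseCv >= 0,
            all(cfg$ticJitter > 0), cfg$ticJitter[2L] >= cfg$ticJitter[1L],
            cfg$nSpectraPerGroup >= 1L, cfg$nReplicates >= 1L,
            !is.null(rownames(cfg$groupEffects)))
  if (any(peakTable$mz < cfg$mzRange[1L] | peakTable$mz > cfg$mzRange[2L]))
    stop("peak outside the m/z grid range")
  if (ncol(cfg$groupEffects) != nrow(cfg$effectRegions))
    stop("groupEffects must have one column per effect region")
  class(cfg) <- "SpectraSimConfig"
  cfg
}

#' Simulate a set of MALDI lipid spectra with known group effects
#'
#' @param cfg a [spectraSimConfig()].
#' @return list with `set` (a [SpectrumSet-class]) and `effects` (long
#'   data.frame of the true multiplicative effect per group and region).
#' @examples
#' sim <- simulateSpectra(spectraSimConfig(nSpectraPerGroup = 3, seed = 2))
#' sim$set
#' @export
simulateSpectra <- function(cfg) {
  stopifnot(inherits(cfg, "SpectraSimConfig"))
  withSeed(cfg$seed, {
    mz <- seq(cfg$mzRange[1L], cfg$mzRange[2L], by = cfg$mzStep)
    sigma <- cfg$peakWidthFwhm / (2 * sqrt(2 * log(2)))
    groups <- rownames(cfg$groupEffects)
    regions <- cfg$effectRegions
    peakRegion <- vapply(cfg$peakTable$mz, function(m) {
      hit <- which(m >= regions$lower & m < regions$upper)
      if (length(hit)) hit[1L] else NA_integer_
    }, integer(1))
    clean <- lapply(groups, function(g) {
      y <- numeric(length(mz))
      for (i in seq_len(nrow(cfg$peakTable))) {
        eff <- if (is.na(peakRegion[i])) 1 else
          cfg$groupEffects[g, peakRegion[i]]
        mu <- cfg$peakTable$mz[i]
        win <- which(mz >= mu - 6 * sigma & mz <= mu + 6 * sigma)
        y[win] <- y[win] + cfg$peakTable$intensity[i] * eff *
          exp(-(mz[win] - mu)^2 / (2 * sigma^2))
      }
      y
    })
    names(clean) <- groups
    sdlog <- sqrt(log(1 + cfg$noiseCv^2))
    spectra <- list(); meta <- list()
    for (g in groups) {
      for (j in seq_len(cfg$nSpectraPerGroup)) {
        tic <- stats::runif(1, cfg$ticJitter[1L], cfg$ticJitter[2L])
        noise <- if (cfg$noiseCv > 0)
          exp(stats::rnorm(length(mz), -sdlog^2 / 2, sdlog)) else 1
        rep_ <- ((j - 1L) %% cfg$nReplicates) + 1L
        spectra[[length(spectra) + 1L]] <-
          MassSpectrum(mz, clean[[g]] * tic * noise)
        meta[[length(meta) + 1L]] <-
          data.frame(sample = sprintf("%s_rep%d", g, rep_),
                     replicate = rep_, group = g,
                     stringsAsFactors = FALSE)
      }
    }
    effects <- do.call(rbind, lapply(groups, function(g)
      data.frame(group = g, region = regions$name,
                 effect = as.numeric(cfg$groupEffects[g, ]),
                 stringsAsFactors = FALSE)))
    list(set = SpectrumSet(spectra, do.call(rbind, meta)), effects = effects)
  })
}
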