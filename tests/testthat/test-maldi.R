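test_that("TIC normalization is exact, idempotent and scale-invariant", {
  s <- MassSpectrum(1:3, c(5, 5, 10))
  n1 <- ticNormalize(s)
  expect_equal(intensityValues(n1), c(0.25, 0.25, 0.50))
  expect_equal(mzValues(n1), mzValues(s))
  expect_equal(intensityValues(ticNormalize(n1)), intensityValues(n1))
  sScaled <- MassSpectrum(1:3, 17.3 * c(5, 5, 10))
  expect_equal(intensityValues(ticNormalize(sScaled)), intensityValues(n1))
  expect_error(ticNormalize(MassSpectrum(1:3, c(0, 0, 0))), "all-zero")
})

test_that("averageSpectra averages onto the grid by linear interpolation", {
  s1 <- MassSpectrum(seq(600, 610, 1), rep(4, 11))
  s2 <- MassSpectrum(seq(600, 610, 1), rep(10, 11))
  meta <- data.frame(sample = c("a", "b"), replicate = 1:2,
                     group = "g")
  avg <- averageSpectra(SpectrumSet(list(s1, s2), meta))
  expect_true(all(abs(intensityValues(avg) - 7) < 1e-12))
  # identical spectra average to themselves
  avg2 <- averageSpectra(SpectrumSet(list(s1, s1), meta))
  expect_equal(intensityValues(avg2), intensityValues(s1))
  # offset grids: compare to hand interpolation at random grid points
  set.seed(5)
  g1 <- seq(600, 610, 0.5); g2 <- seq(600.25, 610.25, 0.5)
  y1 <- runif(length(g1)); y2 <- runif(length(g2))
  sA <- MassSpectrum(g1, y1); sB <- MassSpectrum(g2, y2)
  pts <- sort(runif(20, 600.3, 609.9))
  got <- averageSpectra(SpectrumSet(list(sA, sB), meta), grid = pts)
  oracle <- (handInterp(g1, y1, pts) + handInterp(g2, y2, pts)) / 2
  expect_equal(intensityValues(got), oracle, tolerance = 1e-12)
  # disjoint ranges are an error
  sC <- MassSpectrum(seq(700, 710, 0.5), runif(21))
  expect_error(averageSpectra(SpectrumSet(list(sA, sC), meta)), "disjoint")
})

test_that("averageSpectra commutes with a common TIC scaling", {
  set.seed(9)
  g <- seq(600, 650, 0.5)
  sp <- lapply(1:3, function(i) MassSpectrum(g, runif(length(g))))
  meta <- data.frame(sample = letters[1:3], replicate = 1:3, group = "g")
  a <- averageSpectra(SpectrumSet(sp, meta))
  spScaled <- lapply(sp, function(s)
    MassSpectrum(mzValues(s), 3.7 * intensityValues(s)))
  b <- averageSpectra(SpectrumSet(spScaled, meta))
  expect_equal(3.7 * intensityValues(a), intensityValues(b),
               tolerance = 1e-12)
})

test_that("region scheme routes point masses and honors half-open bounds", {
  grid <- seq(600, 1500, 0.5)
  mkSpike <- function(at) {
    y <- numeric(length(grid)); y[which.min(abs(grid - at))] <- 100
    MassSpectrum(grid, y)
  }
  for (case in list(c(700, 1), c(900, 2), c(1400, 3))) {
    ri <- regionIntensity(mkSpike(case[1]))
    expect_true(ri[case[2]] > 0)
    expect_true(all(ri[-case[2]] == 0))
  }
  # 825 is on the Region1/Region2 boundary: half-open puts it in Region 2
  ri <- regionIntensity(mkSpike(825))
  expect_equal(unname(ri["Region1"]), 0)
  expect_gt(ri[["Region2"]], 0)
  # a region entirely outside the spectrum yields 0 with a warning
  short <- MassSpectrum(seq(600, 900, 0.5), rep(1, 601))
  expect_warning(ri2 <- regionIntensity(short), "Region3")
  expect_equal(unname(ri2["Region3"]), 0)
})

test_that("region integrals of synthetic Gaussians match closed-form masses", {
  grid <- seq(600, 1500, 0.05)
  sigma <- 0.5 / (2 * sqrt(2 * log(2)))  # FWHM 0.5 Da
  peaks <- data.frame(mz = c(700, 900, 1400), A = c(50, 30, 20))
  y <- numeric(length(grid))
  for (i in 1:3)
    y <- y + peaks$A[i] * exp(-(grid - peaks$mz[i])^2 / (2 * sigma^2))
  ri <- regionIntensity(MassSpectrum(grid, y))
  masses <- peaks$A * sigma * sqrt(2 * pi)
  expect_equal(unname(ri), masses, tolerance = 0.01)
  # nonnegative spectrum: region integrals sum to <= the total integral
  total <- pracma::trapz(grid, y)
  expect_lte(sum(ri), total * (1 + 1e-10))
})

test_that("extractPeak returns the windowed maximum near the target", {
  grid <- seq(615, 620, 0.01)
  y <- 7 * exp(-(grid - 616.47)^2 / (2 * 0.08^2))
  s <- MassSpectrum(grid, y)
  expect_equal(extractPeak(s, 616.47), 7, tolerance = 1e-3)
  expect_equal(extractPeak(MassSpectrum(grid, rep(0, length(grid))),
                           616.47), 0)
  # two peaks 0.5 Da apart: tol 0.2 isolates the targeted one
  y2 <- y + 20 * exp(-(grid - 616.97)^2 / (2 * 0.08^2))
  s2 <- MassSpectrum(grid, y2)
  win <- grid >= 616.27 & grid <= 616.67
  expect_equal(extractPeak(s2, 616.47), max(y2[win]))
  expect_lt(extractPeak(s2, 616.47), 19)
  expect_error(extractPeak(s2, 630, tol = 0.2), "no grid points")
  # integral mode matches the trapezoid over the window
  expect_equal(extractPeak(s2, 616.47, mode = "integral"),
               pracma::trapz(grid[win], y2[win]))
})

test_that("the annotation table returns the four diagnostic assignments", {
  expect_equal(annotateLipid(616.47)$species, "CerP(d16:1/18:0)")
  expect_equal(annotateLipid(773.0)$species, "PG(18:1/18:1)")
  expect_equal(annotateLipid(797.67)$species, "SM(d18:1/24:1)")
  expect_equal(annotateLipid(819.0)$species, "PG(18:1/22:6)")
  expect_equal(annotateLipid(773.0)$class, "PG")
  expect_null(annotateLipid(500.0))
  # the cardiolipin region annotates at class level
  expect_equal(annotateLipid(1400.0)$class, "CL")
})

test_that("peakGroupSummary recovers injected effects and output shape", {
  eff <- rbind(control = c(1, 1, 1), senescent = c(2, 1, 1))
  sim <- simulateSpectra(spectraSimConfig(
    groupEffects = eff, nSpectraPerGroup = 30L, seed = 44))
  res <- peakGroupSummary(sim$set, c(773, 819))
  expect_equal(nrow(res$values), 2L * length(sim$set))
  cmp <- res$comparisons
  expect_equal(nrow(cmp), 2L)
  expect_true(all(cmp$p_value < 0.01))
  expect_true(all(cmp$direction == "up"))
  # duplicated groups: p = 1 everywhere
  half <- sim$set[spectrumGroups(sim$set) == "control"]
  dup <- SpectrumSet(c(spectraList(half), spectraList(half)),
                     rbind(within(sampleData(half), group <- "g1"),
                           within(sampleData(half), group <- "g2")))
  res2 <- peakGroupSummary(dup, c(773, 819))
  expect_true(all(res2$comparisons$p_value == 1))
})

test_that("replicate averaging collapses to one spectrum per replicate", {
  sim <- simulateSpectra(spectraSimConfig(nSpectraPerGroup = 6L,
                                          nReplicates = 3L, seed = 2))
  avg <- averageReplicates(sim$set)
  expect_equal(length(avg), 9L)  # 3 groups x 3 replicates
  expect_setequal(as.character(unique(spectrumGroups(avg))),
                  c("control", "doxorubicin", "radiation"))
})
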