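# Independent brute-force oracles used across test files. These never call
# the implementation paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, nx)
# group assignments of the combined sample (tie-free inputs).
enumMwu <- function(x, y) {
  comb <- c(x, y)
  n <- length(comb); nx <- length(x)
  uStat <- function(idx) {
    xs <- comb[idx]; ys <- comb[-idx]
    sum(outer(xs, ys, ">"))
  }
  uObs <- uStat(seq_len(nx))
  us <- apply(utils::combn(n, nx), 2L, uStat)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  list(U = uObs, p = min(1, 2 * min(pLo, pHi)))
}

# Closed-form pooled-variance two-sample t-test.
handStudentT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

# Pointwise linear interpolation by the hand formula.
handInterp <- function(x, y, x0) {
  vapply(x0, function(p) {
    i <- max(which(x <= p))
    if (x[i] == p) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (p - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# Sort-based neighborhood median at one pixel (edge-replicated 3x3).
bruteMedian3 <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  rr <- pmin(pmax((r - 1):(r + 1), 1), H)
  cc <- pmin(pmax((c - 1):(c + 1), 1), W)
  stats::median(as.vector(img[rr, cc]))
}

posKey <- function(m) paste(m[, 1], m[, 2])

# Small noiseless TPEF field used by several imaging tests.
smoothField <- function(n = 64, seed = 11) {
  sim <- simulateTpefImage(tpefSimConfig(
    imageSize = c(n, n), nCells = 3L, backgroundSd = 0,
    nOutliers = 0L, serpentineShift = 0L, seed = seed))
  list(img = channelMatrix(sim$image), mask = sim$mask, truth = sim$truth)
}
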