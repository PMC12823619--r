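# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All package randomness flows through this.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up integer rounding (round(0.5) -> 1), used for printed percentages.
halfUp <- function(x) floor(x + 0.5)

# Circularly rotate a vector right by s positions (s may be negative).
rotateVec <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else c(v[(n - s + 1L):n], v[1L:(n - s)])
}

# Circularly rotate selected rows of a matrix right by s.
rotateRows <- function(m, rows, s) {
  if (length(rows) == 0L || s %% ncol(m) == 0) return(m)
  m[rows, ] <- t(apply(m[rows, , drop = FALSE], 1L, rotateVec, s = s))
  m
}

# Stack the w x w neighborhood of every pixel into an (H*W) x w^2 matrix,
# padding the image border by edge replication.
neighborhoodStack <- function(m, w = 3L) {
  r <- (w - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, H * W, w * w)
  k <- 1L
  for (dc in 0:(w - 1L)) for (dr in 0:(w - 1L)) {
    out[, k] <- as.vector(pad[(1L + dr):(H + dr), (1L + dc):(W + dc)])
    k <- k + 1L
  }
  out
}

# Rowwise median of a 9-column matrix via a sorting network (exact, fast).
rowMedian9 <- function(x) {
  stopifnot(ncol(x) == 9L)
  cx <- function(i, j) {
    lo <- pmin(x[, i], x[, j]); hi <- pmax(x[, i], x[, j])
    x[, i] <<- lo; x[, j] <<- hi
  }
  # median-of-9 network (Paeth); leaves the median in column 5
  cx(2,3); cx(5,6); cx(8,9); cx(1,2); cx(4,5); cx(7,8)
  cx(2,3); cx(5,6); cx(8,9); cx(1,4); cx(6,9); cx(5,8)
  cx(4,7); cx(2,5); cx(3,6); cx(5,8); cx(5,3); cx(7,5); cx(5,3)
  x[, 5L]
}

# Rowwise median for arbitrary (small) column counts.
rowMedianK <- function(x) {
  if (ncol(x) == 9L) return(rowMedian9(x))
  apply(x, 1L, stats::median)
}
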