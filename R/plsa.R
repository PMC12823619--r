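#' Bin spectra into a document-term matrix
#'
#' TIC-normalizes every spectrum and sums its intensity into fixed-width
#' m/z bins, producing the spectra-by-bins nonnegative weight matrix the
#' pLSA factorization operates on (documents = spectra, terms = m/z
#' bins). Every row sums to 1 (the normalized TIC); bins that are zero in
#' all spectra are dropped.
#'
#' @param set a [SpectrumSet-class].
#' @param binWidth bin width in Da, > 0 (default 1).
#' @return numeric matrix (docs x bins) with bin centers as column names
#'   and attributes `binCenters` and `groups`.
#' @seealso [plsaFit()]
#' @export
binSpectra <- function(set, binWidth = 1) {
  stopifnot(is(set, "SpectrumSet"), binWidth > 0)
  nset <- ticNormalize(set)
  allLo <- min(vapply(nset@spectra, function(s) min(s@mz), numeric(1)))
  allHi <- max(vapply(nset@spectra, function(s) max(s@mz), numeric(1)))
  if (binWidth >= allHi - allLo)
    stop("binWidth larger than the m/z span of the spectra")
  origin <- floor(allLo / binWidth) * binWidth
  nBins <- floor((allHi - origin) / binWidth) + 1L
  dtm <- t(vapply(nset@spectra, function(s) {
    idx <- floor((s@mz - origin) / binWidth) + 1L
    as.numeric(rowsum(s@intensity, factor(idx, levels = seq_len(nBins))))
  }, numeric(nBins)))
  keep <- colSums(dtm) > 0
  dtm <- dtm[, keep, drop = FALSE]
  centers <- origin + (which(keep) - 0.5) * binWidth
  dimnames(dtm) <- list(sprintf("spectrum%d", seq_len(nrow(dtm))),
                        sprintf("%.1f", centers))
  attr(dtm, "binCenters") <- centers
  attr(dtm, "groups") <- as.character(spectrumGroups(set))
  dtm
}

#' Fit probabilistic latent semantic analysis by EM
#'
#' Plain (untempered) pLSA on a nonnegative document-term matrix `N`: the
#' model `P(d, w) = sum_z P(z|d) P(w|z)` is fitted by
#' expectation-maximization. The E-step forms the posterior over topics
#' for every (document, term) pair; the M-step reestimates the
#' topic-conditional term distributions and document-conditional topic
#' distributions from posterior-weighted counts. Continuous weights (such
#' as TIC-normalized intensities) are used as-is — pLSA's updates only
#' require nonnegativity. The log-likelihood
#' `sum_dw N[d,w] log sum_z P(z|d) P(w|z)` is non-decreasing across
#' iterations by EM construction.
#'
#' Both distributions are initialized from symmetric Dirichlet(1) draws;
#' `restarts` independent initializations (seeds `seed`, `seed + 1`, ...)
#' are run and the fit with the best final log-likelihood is kept.
#'
#' @param dtm nonnegative numeric matrix (docs x terms); every document
#'   must have positive total weight. Group labels are never read.
#' @param K number of topics, `1 <= K <= min(docs, terms)`.
#' @param seed integer seed for initialization.
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param relTol relative log-likelihood change for convergence
#'   (default 1e-6).
#' @param restarts number of random restarts (default 5).
#' @return a [PLSAModel-class].
#' @examples
#' N <- matrix(c(4, 0, 1, 5), 2, 2)
#' plsaFit(N, K = 1, seed = 1)
#' @export
plsaFit <- function(dtm, K, seed = 1L, maxIter = 500L, relTol = 1e-6,
                    restarts = 5L) {
  N <- as.matrix(dtm)
  if (any(N < 0) || any(!is.finite(N))) stop("weights must be finite, >= 0")
  D <- nrow(N); W <- ncol(N)
  K <- as.integer(K)
  if (K < 1L || K > min(D, W))
    stop("K must satisfy 1 <= K <= min(docs, terms)")
  nd <- rowSums(N)
  if (any(nd <= 0)) stop("document with zero total weight")
  pos <- N > 0
  best <- NULL
  for (r in seq_len(restarts)) {
    rs <- as.integer(seed) + r - 1L
    init <- withSeed(rs, {
      theta <- matrix(stats::rgamma(D * K, 1), D, K)
      phi <- matrix(stats::rgamma(W * K, 1), W, K)
      list(theta = theta / rowSums(theta),
           phi = sweep(phi, 2L, colSums(phi), "/"))
    })
    theta <- init$theta; phi <- init$phi
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      P <- theta %*% t(phi)
      ll <- sum(N[pos] * log(P[pos]))
      trace <- c(trace, ll)
      if (it > 1L &&
          abs(ll - trace[it - 1L]) < relTol * abs(trace[it - 1L])) {
        converged <- TRUE
        break
      }
      R <- N / P
      R[!pos] <- 0
      phiNew <- phi * (t(R) %*% theta)
      cs <- colSums(phiNew)
      cs[cs == 0] <- 1
      phi <- sweep(phiNew, 2L, cs, "/")
      thetaNew <- theta * (R %*% phi)
      theta <- thetaNew / rowSums(thetaNew)
    }
    fit <- list(theta = theta, phi = phi, trace = trace, seed = rs,
                nIter = length(trace), converged = converged)
    if (is.null(best) ||
        fit$trace[fit$nIter] > best$trace[best$nIter]) best <- fit
  }
  new("PLSAModel", K = K,
      termGivenTopic = best$phi, topicGivenDoc = best$theta,
      logLik = best$trace, seed = best$seed,
      nIter = as.integer(best$nIter), converged = best$converged)
}

#' Class separation of a fitted pLSA model in topic space
#'
#' Projects every document onto its topic loadings P(z|d), computes
#' per-class centroids from the supplied labels, assigns each document to
#' the nearest centroid (Euclidean distance) and reports the resulting
#' accuracy together with the mean silhouette width of the labeled
#' grouping in topic space. Deterministic given the model. With a single
#' class, accuracy is undefined (`NA`) and only the silhouette slot is
#' meaningful; a K = 1 model gives every document identical loadings, so
#' the silhouette is undefined and reported as `NA`.
#'
#' @param model a fitted [PLSAModel-class].
#' @param labels character or factor of true class labels, one per
#'   document.
#' @return list with `loadings` (data.frame: document, label, assigned,
#'   one column per topic), `accuracy`, `silhouette` (mean width) and
#'   `confusion` (table of label x assigned).
#' @export
discriminateTopics <- function(model, labels) {
  stopifnot(is(model, "PLSAModel"))
  theta <- topicGivenDoc(model)
  labels <- factor(labels)
  if (length(labels) != nrow(theta))
    stop("labels must cover all documents")
  nCls <- nlevels(labels)
  centroids <- rowsum(theta, labels) / as.vector(table(labels))
  d2 <- outer(rowSums(theta^2), rep(1, nCls)) -
    2 * theta %*% t(centroids) +
    outer(rep(1, nrow(theta)), rowSums(centroids^2))
  assigned <- levels(labels)[apply(d2, 1L, which.min)]
  accuracy <- if (nCls < 2L) NA_real_ else
    mean(assigned == as.character(labels))
  silhouette <- NA_real_
  if (nCls >= 2L && model@K >= 2L) {
    dd <- stats::dist(theta)
    if (max(dd) > 0) {
      sil <- cluster::silhouette(as.integer(labels), dd)
      silhouette <- mean(sil[, "sil_width"])
    }
  }
  loadings <- data.frame(document = rownames(theta) %||%
                           sprintf("doc%d", seq_len(nrow(theta))),
                         label = as.character(labels),
                         assigned = assigned, stringsAsFactors = FALSE)
  colnames(theta) <- sprintf("topic%d", seq_len(ncol(theta)))
  loadings <- cbind(loadings, as.data.frame(theta))
  list(loadings = loadings, accuracy = accuracy, silhouette = silhouette,
       confusion = table(label = labels, assigned = assigned))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
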