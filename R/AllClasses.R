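#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Multi-channel fluorescence image
#'
#' Container for one field of view acquired in one or more channels
#' (e.g. a TPEF autofluorescence channel plus a transmission channel, or a
#' JC-1 red/green pair). All channels are numeric matrices in arbitrary
#' fluorescence units (a.u.), share dimensions and are indexed row-major
#' with 0-based pixel coordinates reported in outputs.
#'
#' @slot channels named list of numeric matrices, one per channel.
#' @slot roles character vector naming the role of each channel
#'   (e.g. `"tpef"`, `"transmission"`, `"red"`, `"green"`).
#'
#' @seealso [channelMatrix()], [removeOutliers()], [deskewSerpentine()]
#' @export
setClass("MultiChannelImage",
  slots = c(channels = "list", roles = "character"))

setValidity("MultiChannelImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("all channels must be matrices")
  d <- dim(ch[[1L]])
  if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1))))
    return("all channels must share dimensions")
  if (!all(vapply(ch, function(m) all(is.finite(m)), logical(1))))
    return("channel intensities must be finite")
  if (length(object@roles) != length(ch))
    return("one role per channel required")
  TRUE
})

#' Construct a MultiChannelImage
#'
#' @param channels named list of numeric matrices (or a single matrix).
#' @param roles channel roles; defaults to `names(channels)`.
#' @return a [MultiChannelImage-class] object.
#' @examples
#' img <- MultiChannelImage(list(tpef = matrix(runif(64), 8, 8)))
#' dim(img)
#' @export
MultiChannelImage <- function(channels, roles = names(channels)) {
  if (is.matrix(channels)) channels <- list(tpef = channels)
  if (is.null(roles)) roles <- paste0("ch", seq_along(channels))
  names(channels) <- roles
  new("MultiChannelImage", channels = channels, roles = roles)
}

#' @describeIn MultiChannelImage image dimensions (rows, columns).
#' @param x a `MultiChannelImage`.
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@channels[[1L]]))

#' Extract one channel as a matrix
#'
#' @param x a [MultiChannelImage-class].
#' @param role channel role or index; default the first channel.
#' @return numeric matrix.
#' @export
channelMatrix <- function(x, role = 1L) {
  stopifnot(is(x, "MultiChannelImage"))
  if (is.character(role) && !role %in% x@roles)
    stop("no channel with role '", role, "'")
  x@channels[[role]]
}

#' @describeIn MultiChannelImage channel roles.
#' @export
channelRoles <- function(x) x@roles

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat("MultiChannelImage:", d[1L], "x", d[2L], "pixels,",
      length(object@channels), "channel(s):",
      paste(object@roles, collapse = ", "), "\n")
})

#' Single mass spectrum
#'
#' An (m/z, intensity) profile spectrum. The m/z axis is strictly
#' increasing; intensities are finite and nonnegative (a.u., or fractions of
#' total ion count after [ticNormalize()]).
#'
#' @slot mz numeric, strictly increasing m/z values (Da).
#' @slot intensity numeric, nonnegative intensities, same length as `mz`.
#' @seealso [SpectrumSet-class], [ticNormalize()], [extractPeak()]
#' @export
setClass("MassSpectrum", slots = c(mz = "numeric", intensity = "numeric"))

setValidity("MassSpectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (length(object@mz) == 0L) return("empty spectrum")
  if (any(diff(object@mz) <= 0)) return("mz must be strictly increasing")
  if (!all(is.finite(object@intensity)) || any(object@intensity < 0))
    return("intensities must be finite and nonnegative")
  TRUE
})

#' Construct a MassSpectrum
#' @param mz strictly increasing m/z values (Da).
#' @param intensity nonnegative intensities.
#' @return a [MassSpectrum-class] object.
#' @examples
#' s <- MassSpectrum(c(600, 600.5, 601), c(0, 10, 0))
#' totalIonCount(s)
#' @export
MassSpectrum <- function(mz, intensity) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' @describeIn MassSpectrum m/z axis.
#' @param object,x a `MassSpectrum`.
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))
#' @export
setMethod("mzValues", "MassSpectrum", function(x) x@mz)

#' @describeIn MassSpectrum intensity vector.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))
#' @export
setMethod("intensityValues", "MassSpectrum", function(x) x@intensity)

#' @describeIn MassSpectrum sum of intensities (total ion count).
#' @export
totalIonCount <- function(x) sum(intensityValues(x))

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum: %d points, m/z %.2f-%.2f, TIC %.4g\n",
              length(object@mz), min(object@mz), max(object@mz),
              sum(object@intensity)))
})

#' Collection of mass spectra with sample annotation
#'
#' Holds a list of [MassSpectrum-class] objects together with per-spectrum
#' annotation (`sample`, `replicate`, `group`), the unit the MALDI analysis
#' and the pLSA factorization operate on.
#'
#' @slot spectra list of `MassSpectrum` objects.
#' @slot sampleData data.frame with one row per spectrum; columns
#'   `sample`, `replicate`, `group` (group is a factor).
#' @seealso [simulateSpectra()], [peakGroupSummary()], [binSpectra()]
#' @export
setClass("SpectrumSet",
  slots = c(spectra = "list", sampleData = "data.frame"))

setValidity("SpectrumSet", function(object) {
  if (length(object@spectra) == 0L) return("empty spectrum set")
  if (!all(vapply(object@spectra, is, logical(1), "MassSpectrum")))
    return("spectra must be MassSpectrum objects")
  if (nrow(object@sampleData) != length(object@spectra))
    return("sampleData must have one row per spectrum")
  need <- c("sample", "replicate", "group")
  if (!all(need %in% colnames(object@sampleData)))
    return("sampleData needs columns sample, replicate, group")
  TRUE
})

#' Construct a SpectrumSet
#' @param spectra list of [MassSpectrum-class] objects.
#' @param sampleData data.frame with columns `sample`, `replicate`, `group`.
#' @return a [SpectrumSet-class] object.
#' @export
SpectrumSet <- function(spectra, sampleData) {
  sampleData$group <- factor(sampleData$group)
  new("SpectrumSet", spectra = spectra, sampleData = sampleData)
}

#' @describeIn SpectrumSet number of spectra.
#' @param x a `SpectrumSet`.
#' @export
setMethod("length", "SpectrumSet", function(x) length(x@spectra))

#' @describeIn SpectrumSet per-spectrum annotation data.frame.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @export
setMethod("sampleData", "SpectrumSet", function(x) x@sampleData)

#' @describeIn SpectrumSet list of MassSpectrum objects.
#' @export
setGeneric("spectraList", function(x) standardGeneric("spectraList"))
#' @export
setMethod("spectraList", "SpectrumSet", function(x) x@spectra)

#' @describeIn SpectrumSet group factor of the spectra.
#' @export
setGeneric("spectrumGroups", function(x) standardGeneric("spectrumGroups"))
#' @export
setMethod("spectrumGroups", "SpectrumSet", function(x) x@sampleData$group)

#' @describeIn SpectrumSet subset spectra by index or logical vector.
#' @param i index vector.
#' @param j,drop unused.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
  SpectrumSet(x@spectra[i], droplevels(x@sampleData[i, , drop = FALSE]))
})

setMethod("show", "SpectrumSet", function(object) {
  g <- table(object@sampleData$group)
  cat("SpectrumSet:", length(object@spectra), "spectra;",
      paste(sprintf("%s (n=%d)", names(g), g), collapse = ", "), "\n")
})

#' Fitted pLSA topic model
#'
#' Result of the EM fit of probabilistic latent semantic analysis over a
#' spectrum-by-m/z-bin matrix: the topic-conditional term distributions
#' P(w|z), the document-conditional topic distributions P(z|d), and the
#' per-iteration log-likelihood trace (non-decreasing by EM construction).
#'
#' @slot K integer, number of topics.
#' @slot termGivenTopic terms x K matrix; each column sums to 1.
#' @slot topicGivenDoc docs x K matrix; each row sums to 1.
#' @slot logLik numeric log-likelihood trace, one value per EM iteration.
#' @slot seed integer seed the winning restart was initialized from.
#' @slot nIter integer, iterations run by the winning restart.
#' @slot converged logical, whether the relative-tolerance stop was reached.
#' @seealso [plsaFit()], [discriminateTopics()]
#' @export
setClass("PLSAModel",
  slots = c(K = "integer", termGivenTopic = "matrix",
            topicGivenDoc = "matrix", logLik = "numeric",
            seed = "integerOrNULL", nIter = "integer",
            converged = "logical"))

setValidity("PLSAModel", function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (ncol(object@termGivenTopic) != object@K ||
      ncol(object@topicGivenDoc) != object@K)
    return("distribution matrices must have K columns")
  if (any(object@termGivenTopic < 0) || any(object@topicGivenDoc < 0))
    return("distributions must be nonnegative")
  if (max(abs(colSums(object@termGivenTopic) - 1)) > 1e-9)
    return("term_given_topic columns must sum to 1 (tol 1e-9)")
  if (max(abs(rowSums(object@topicGivenDoc) - 1)) > 1e-9)
    return("topic_given_doc rows must sum to 1 (tol 1e-9)")
  TRUE
})

#' @describeIn PLSAModel docs x K matrix of topic loadings P(z|d).
#' @param x a `PLSAModel`.
#' @export
setGeneric("topicGivenDoc", function(x) standardGeneric("topicGivenDoc"))
#' @export
setMethod("topicGivenDoc", "PLSAModel", function(x) x@topicGivenDoc)

#' @describeIn PLSAModel terms x K matrix of term distributions P(w|z).
#' @export
setGeneric("termGivenTopic", function(x) standardGeneric("termGivenTopic"))
#' @export
setMethod("termGivenTopic", "PLSAModel", function(x) x@termGivenTopic)

#' @describeIn PLSAModel per-iteration log-likelihood trace.
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))
#' @export
setMethod("logLikTrace", "PLSAModel", function(x) x@logLik)

setMethod("show", "PLSAModel", function(object) {
  cat(sprintf(
    "PLSAModel: K=%d, %d docs x %d terms, %d EM iterations (%s), logLik %.4f\n",
    object@K, nrow(object@topicGivenDoc), nrow(object@termGivenTopic),
    object@nIter, if (object@converged) "converged" else "max_iter",
    object@logLik[length(object@logLik)]))
})
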