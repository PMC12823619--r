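#' Write and read images as TIFF
#'
#' Images are stored as 32-bit float (multi-page for multiple channels);
#' label masks as 16-bit integer TIFF. TIFF stores values in \[0, 1\], so
#' intensities are divided by an explicit calibration divisor written to a
#' `<path>.scale.txt` sidecar and restored on read — the a.u. scale is
#' preserved (to 32-bit float precision) rather than silently
#' renormalized, because the 0.25 a.u. signal threshold is absolute.
#'
#' @param x a matrix or [MultiChannelImage-class].
#' @param path file path.
#' @param scale calibration divisor; default `max(1, max(x))`.
#' @return `writeImageTiff` returns `path` invisibly; `readImageTiff`
#'   returns a [MultiChannelImage-class].
#' @export
writeImageTiff <- function(x, path, scale = NULL) {
  if (is.matrix(x)) x <- MultiChannelImage(list(tpef = x))
  if (is.null(scale))
    scale <- max(1, vapply(x@channels, max, numeric(1)))
  tiff::writeTIFF(lapply(unname(x@channels), function(m) m / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(format(scale, digits = 17), paste0(path, ".scale.txt"))
  invisible(path)
}

#' @rdname writeImageTiff
#' @param roles channel roles to assign on read; default `ch1`, `ch2`, ...
#' @export
readImageTiff <- function(path, roles = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scaleFile <- paste0(path, ".scale.txt")
  scale <- if (file.exists(scaleFile))
    as.numeric(readLines(scaleFile)[1L]) else 1
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * scale
  })
  if (is.null(roles)) roles <- paste0("ch", seq_along(pages))
  MultiChannelImage(pages, roles = roles)
}

#' @rdname writeImageTiff
#' @param mask integer label matrix (labels 0..65535).
#' @export
writeLabelMaskTiff <- function(mask, path) {
  stopifnot(max(mask) <= 65535L, min(mask) >= 0L)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readLabelMaskTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write and read a SpectrumSet as CSV files plus a manifest
#'
#' Each spectrum is written as a two-column CSV (`mz`, `intensity`); a
#' tab-separated `manifest.tsv` (columns `file`, `sample`, `replicate`,
#' `group`) indexes them. This plain-text layout is the canonical
#' interchange format of the MALDI module.
#'
#' @param set a [SpectrumSet-class].
#' @param dir output directory (created if missing).
#' @return `writeSpectrumSet` returns the manifest path invisibly;
#'   `readSpectrumSet` returns a [SpectrumSet-class].
#' @export
writeSpectrumSet <- function(set, dir) {
  stopifnot(is(set, "SpectrumSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sd_ <- sampleData(set)
  files <- sprintf("spectrum_%04d.csv", seq_len(length(set)))
  for (i in seq_len(length(set))) {
    s <- set@spectra[[i]]
    utils::write.csv(data.frame(mz = s@mz, intensity = s@intensity),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- data.frame(file = files, sample = sd_$sample,
                         replicate = sd_$replicate,
                         group = as.character(sd_$group),
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' @rdname writeSpectrumSet
#' @param manifestPath path to a manifest TSV.
#' @export
readSpectrumSet <- function(manifestPath) {
  manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  dir <- dirname(manifestPath)
  spectra <- lapply(manifest$file, function(f) {
    d <- utils::read.csv(file.path(dir, f))
    MassSpectrum(d$mz, d$intensity)
  })
  SpectrumSet(spectra, manifest[, c("sample", "replicate", "group")])
}
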