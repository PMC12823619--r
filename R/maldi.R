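#' The three diagnostic m/z regions of the lipid profile
#'
#' Region 1 (m/z 600-825) is dominated by mixed phosphatides (PC, PE, SM),
#' Region 2 (825-950) by phosphatidylinositols, and Region 3 (1300-1500)
#' by cardiolipins, which are exclusive to mitochondrial membranes.
#' Boundaries are half-open `[lower, upper)`: 825 belongs to Region 2,
#' 950 to no region, 1300 to Region 3.
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
defaultRegions <- function() {
  data.frame(name = c("Region1", "Region2", "Region3"),
             lower = c(600, 825, 1300),
             upper = c(825, 950, 1500),
             stringsAsFactors = FALSE)
}

validateRegions <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("name", "lower", "upper") %in% colnames(scheme)),
            all(scheme$upper > scheme$lower))
  o <- order(scheme$lower)
  scheme <- scheme[o, , drop = FALSE]
  if (nrow(scheme) > 1L &&
      any(scheme$lower[-1L] < scheme$upper[-nrow(scheme)]))
    stop("regions must not overlap")
  scheme
}

#' Normalize a spectrum to total ion count
#'
#' Scales intensities so they sum to 1, removing per-spot intensity bias.
#' Idempotent and invariant to any positive rescaling of the input.
#'
#' @param x a [MassSpectrum-class] or [SpectrumSet-class] (each spectrum
#'   normalized independently).
#' @return object of the same class.
#' @examples
#' ticNormalize(MassSpectrum(1:3, c(5, 5, 10)))
#' @export
setGeneric("ticNormalize", function(x) standardGeneric("ticNormalize"))

#' @rdname ticNormalize
#' @export
setMethod("ticNormalize", "MassSpectrum", function(x) {
  tic <- sum(x@intensity)
  if (tic <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  MassSpectrum(x@mz, x@intensity / tic)
})

#' @rdname ticNormalize
#' @export
setMethod("ticNormalize", "SpectrumSet", function(x) {
  SpectrumSet(lapply(x@spectra, ticNormalize), x@sampleData)
})

#' Average spectra onto a common m/z grid
#'
#' Linearly interpolates every spectrum onto `grid` and takes the
#' pointwise arithmetic mean — the per-experiment averaging step applied
#' to the hundreds of pixel spectra before statistics. The default grid
#' spans the intersection of the input ranges at the median native
#' spacing; supplying a grid outside that intersection is an error, as is
#' a set of spectra with disjoint m/z ranges.
#'
#' @param set a [SpectrumSet-class] (>= 1 spectrum).
#' @param grid optional numeric m/z grid, strictly increasing.
#' @return a [MassSpectrum-class].
#' @export
averageSpectra <- function(set, grid = NULL) {
  stopifnot(is(set, "SpectrumSet"), length(set) >= 1L)
  lo <- max(vapply(set@spectra, function(s) min(s@mz), numeric(1)))
  hi <- min(vapply(set@spectra, function(s) max(s@mz), numeric(1)))
  if (lo >= hi) stop("spectra have disjoint m/z ranges")
  if (is.null(grid)) {
    step <- stats::median(vapply(set@spectra,
                                 function(s) stats::median(diff(s@mz)),
                                 numeric(1)))
    grid <- seq(lo, hi, by = step)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) < lo || max(grid) > hi)
    stop("grid must lie within the overlap of all input spectra")
  acc <- rowMeans(vapply(set@spectra, function(s)
    stats::approx(s@mz, s@intensity, xout = grid)$y, numeric(length(grid))))
  MassSpectrum(grid, acc)
}

#' Average spectra within each biological replicate
#'
#' Collapses the set to one averaged spectrum per (group, replicate)
#' combination — the granularity used for statistics across biological
#' replicates — while the original per-spectrum set remains available for
#' box-plot style per-spectrum summaries.
#'
#' @param set a [SpectrumSet-class].
#' @param grid optional common grid passed to [averageSpectra()].
#' @return a [SpectrumSet-class] with one spectrum per replicate.
#' @export
averageReplicates <- function(set, grid = NULL) {
  sd_ <- sampleData(set)
  key <- interaction(sd_$group, sd_$replicate, drop = TRUE)
  idx <- split(seq_len(length(set)), key)
  spectra <- lapply(idx, function(i) averageSpectra(set[i], grid))
  meta <- do.call(rbind, lapply(idx, function(i)
    data.frame(sample = sd_$sample[i[1L]], replicate = sd_$replicate[i[1L]],
               group = as.character(sd_$group[i[1L]]),
               stringsAsFactors = FALSE)))
  SpectrumSet(unname(spectra), meta)
}

#' Integrated intensity per m/z region
#'
#' Trapezoidal integral of the spectrum over each half-open region
#' `[lower, upper)`. Regions that contain no grid points yield 0 with a
#' warning.
#'
#' @param s a [MassSpectrum-class].
#' @param scheme region scheme data.frame (`name`, `lower`, `upper`);
#'   default [defaultRegions()].
#' @return named numeric vector of integrals, one per region.
#' @export
regionIntensity <- function(s, scheme = defaultRegions()) {
  stopifnot(is(s, "MassSpectrum"))
  scheme <- validateRegions(scheme)
  out <- vapply(seq_len(nrow(scheme)), function(i) {
    sel <- s@mz >= scheme$lower[i] & s@mz < scheme$upper[i]
    if (sum(sel) < 2L) {
      warning("region ", scheme$name[i],
              " contains fewer than 2 grid points; integral set to 0")
      return(0)
    }
    pracma::trapz(s@mz[sel], s@intensity[sel])
  }, numeric(1))
  names(out) <- scheme$name
  out
}

#' Extract a peak intensity at a target m/z
#'
#' Returns the maximum intensity within `[target - tol, target + tol]`
#' (the "peak intensity" convention of MALDI box plots); an integral mode
#' (trapezoid over the window) is available by flag. The default
#' tolerance of 0.2 Da reflects the instrument class: a resolving power
#' of about 5000 at m/z 885.56 corresponds to a FWHM of roughly 0.18 Da.
#'
#' @param s a [MassSpectrum-class].
#' @param targetMz target m/z (Da).
#' @param tol half-window (Da), > 0; default 0.2.
#' @param mode `"max"` (default) or `"integral"`.
#' @return scalar intensity.
#' @examples
#' s <- MassSpectrum(seq(616, 617, 0.01),
#'                   exp(-(seq(616, 617, 0.01) - 616.47)^2 / 0.005))
#' extractPeak(s, 616.47)
#' @export
extractPeak <- function(s, targetMz, tol = 0.2,
                        mode = c("max", "integral")) {
  mode <- match.arg(mode)
  stopifnot(is(s, "MassSpectrum"), tol > 0)
  sel <- s@mz >= targetMz - tol & s@mz <= targetMz + tol
  if (!any(sel))
    stop("no grid points within ", tol, " Da of m/z ", targetMz)
  if (mode == "max") max(s@intensity[sel])
  else if (sum(sel) < 2L) 0
  else pracma::trapz(s@mz[sel], s@intensity[sel])
}

#' Shipped lipid annotation table
#'
#' The diagnostic negative-ion-mode assignments: CerP (d16:1/18:0) at m/z
#' 616.47, PG (18:1/18:1) at 773, SM (d18:1/24:1) at 797.67 and PG
#' (18:1/22:6) at 819; peaks in the 1300-1500 region are assigned to the
#' cardiolipin class without a species-level call.
#'
#' @return data.frame with columns `mz`, `species`, `class`.
#' @export
lipidAnnotations <- function() {
  data.frame(mz = c(616.47, 773.00, 797.67, 819.00),
             species = c("CerP(d16:1/18:0)", "PG(18:1/18:1)",
                         "SM(d18:1/24:1)", "PG(18:1/22:6)"),
             class = c("CerP", "PG", "SM", "PG"),
             stringsAsFactors = FALSE)
}

#' Annotate a peak m/z against the lipid table
#'
#' Nearest table entry within `tol`; m/z in the cardiolipin region
#' (1300-1500) with no species-level match is annotated as class `"CL"`.
#'
#' @param targetMz query m/z (Da).
#' @param table annotation table, default [lipidAnnotations()].
#' @param tol match tolerance (Da), default 0.2.
#' @return one-row data.frame (`mz`, `species`, `class`) or `NULL` when
#'   nothing matches.
#' @examples
#' annotateLipid(773.0)$species
#' annotateLipid(500.0)  # NULL
#' @export
annotateLipid <- function(targetMz, table = lipidAnnotations(), tol = 0.2) {
  d <- abs(table$mz - targetMz)
  i <- which.min(d)
  if (length(i) && d[i] <= tol) return(table[i, , drop = FALSE])
  if (targetMz >= 1300 && targetMz < 1500)
    return(data.frame(mz = targetMz, species = NA_character_,
                      class = "CL", stringsAsFactors = FALSE))
  NULL
}

#' Per-peak group summary and tests
#'
#' TIC-normalizes every spectrum, extracts each requested peak from each
#' spectrum, and compares every non-control group against the control by
#' two-sided Mann-Whitney U tests per peak. Peaks whose window is empty
#' or zero in all spectra are skipped with a warning.
#'
#' @param set a [SpectrumSet-class] with >= 2 groups.
#' @param peaks numeric vector of target m/z values.
#' @param control name of the reference group; default the first factor
#'   level.
#' @param tol peak half-window (Da), default 0.2.
#' @param mode peak value mode, see [extractPeak()].
#' @return list with `values` (long data.frame: `spectrum`, `sample`,
#'   `replicate`, `group`, `mz`, `intensity`) and `comparisons` (per peak
#'   and group vs control: U, two-sided p, method, `direction` — `"up"`
#'   when the group's median exceeds the control's).
#' @export
peakGroupSummary <- function(set, peaks, control = NULL, tol = 0.2,
                             mode = c("max", "integral")) {
  mode <- match.arg(mode)
  stopifnot(is(set, "SpectrumSet"), length(peaks) >= 1L)
  grp <- spectrumGroups(set)
  if (nlevels(grp) < 2L) stop("need >= 2 groups")
  if (is.null(control)) control <- levels(grp)[1L]
  if (!control %in% levels(grp)) stop("unknown control group: ", control)
  nset <- ticNormalize(set)
  sd_ <- sampleData(nset)
  values <- do.call(rbind, lapply(seq_along(peaks), function(j) {
    ints <- vapply(nset@spectra, function(s)
      tryCatch(extractPeak(s, peaks[j], tol, mode),
               error = function(e) NA_real_), numeric(1))
    data.frame(spectrum = seq_len(length(nset)), sample = sd_$sample,
               replicate = sd_$replicate, group = as.character(grp),
               mz = peaks[j], intensity = ints, stringsAsFactors = FALSE)
  }))
  comparisons <- list()
  for (j in seq_along(peaks)) {
    vj <- values[values$mz == peaks[j], ]
    if (all(is.na(vj$intensity)) || all(vj$intensity == 0, na.rm = TRUE)) {
      warning("peak m/z ", peaks[j], " absent from all spectra; skipped")
      next
    }
    ctrl <- vj$intensity[vj$group == control]
    for (g in setdiff(levels(grp), control)) {
      xg <- vj$intensity[vj$group == g]
      cmp <- mannWhitneyU(xg, ctrl)
      cmp$metric <- sprintf("peak_%.2f", peaks[j])
      cmp$group_a <- g; cmp$group_b <- control
      cmp$mz <- peaks[j]
      cmp$direction <- if (stats::median(xg, na.rm = TRUE) >
                           stats::median(ctrl, na.rm = TRUE)) "up" else "down"
      comparisons[[length(comparisons) + 1L]] <- cmp
    }
  }
  list(values = values,
       comparisons = if (length(comparisons)) do.call(rbind, comparisons)
         else NULL)
}
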