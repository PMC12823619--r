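---
title: "Profiling therapy-induced senescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling therapy-induced senescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senometrix)
```

Cancer cells that survive chemotherapy or irradiation can enter
therapy-induced senescence: a stable proliferation arrest accompanied by
extensive mitochondrial and metabolic remodeling. This package implements
three quantitative readouts of that state — label-free two-photon excited
fluorescence (TPEF) imaging of the metabolic cofactors NAD(P)H and FAD,
JC-1 mitochondrial membrane-potential ratiometry, and MALDI-TOF lipid
profiling with unsupervised group discrimination — together with synthetic
generators that make every stage testable against known ground truth.
This vignette records the models, the tunable parameters, and the design
choices made where the procedures left genuine freedom.

## TPEF imaging and the Aggregation Index

The TPEF channel records endogenous autofluorescence of NAD(P)H and FAD in
arbitrary units (a.u.). Per segmented cell the pipeline computes

$$\mathrm{AI} \;=\; \frac{\text{Max TPEF signal [a.u.]}}
{[\text{Area}_\mathrm{TPEF} / \text{Area}_\mathrm{Cell}]\,\%},$$

where *Max TPEF* is the mean of the top 10% highest pixel values of the
cell (count `ceiling(0.1 n)`; cells under 10 pixels are rejected) and the
denominator is the percentage of the cell area whose intensity reaches the
absolute threshold of 0.25 a.u. A high AI means the cofactor signal is
concentrated in bright aggregates; dispersal of the signal through the
cytosol — the senescent phenotype — lowers it. Both quantities are
computed per cell, not per field of view, because the downstream statistics
compare distributions over cells.

Preprocessing runs in a fixed order before any metric: outlier removal,
serpentine deskew, thresholding.

**1-pixel outlier removal.** Cosmic rays produce isolated bright pixels and
detector dropouts isolated dark ones. A pixel is flagged when it is a
strict extremum of its 3×3 neighborhood *and* the gap between it and its
nearest neighbor value exceeds `madFactor` (default 5) times the scaled
MAD of the neighborhood, floored at `minDeviation = 0.05` a.u. We chose
the gap-to-nearest-neighbor form over the more common deviation-from-median
form deliberately: a sharp but smooth intensity peak always has a close
companion value on its own ridge, so the gap criterion leaves genuine
structure untouched, whereas the median form can fire on anisotropic peak
tops whose clustered mid-values shrink the local MAD. The absolute floor
keeps noise-free flat regions (MAD = 0) from flagging negligible
fluctuations; 0.05 a.u. sits well below the 0.25 a.u. signal threshold and
above typical detector noise excursions. Flagged pixels are replaced by
their neighborhood median and passes repeat until no pixel qualifies
(almost always one or two), which makes the operation exactly idempotent.
Border pixels are edge-replicated and can never be strict extrema.

**Serpentine deskew.** Bidirectional raster scanning shifts alternate
lines sideways. The estimator searches the single integer shift
$s \in [-s_{\max}, s_{\max}]$ maximizing the mean Pearson correlation
between each even row circularly shifted by $s$ and the average of its
adjacent odd rows, then applies it to the even rows. Circular shifts are
exactly invertible, so no information is lost. Ties are broken toward
smaller $|s|$, then toward negative $s$; a constant image returns shift 0
with a `degenerate` flag. The procedure assumes one global shift per
image, which matches a stage with a constant turnaround lag.

**Absolute threshold.** The 0.25 a.u. cut is absolute, so the pipeline
never rescales intensities silently; images not already on the
instrument's a.u. scale must be divided by a user-supplied calibration
factor first. A documented consequence, covered by a property test, is
that the AI is *not* invariant under intensity rescaling. Cells with no
above-threshold pixel get a flagged record with a missing (not zero) AI.

Group differences in AI and in area fraction are assessed with two-sided
Mann–Whitney U tests.

## JC-1 ratiometry

JC-1 accumulates and dimerizes in polarized mitochondria (red
fluorescence); depolarization leaves green monomers. Per cell the ratio
mean(red)/mean(green) is computed over the label mask; cells with a
non-positive green mean are flagged rather than producing infinities.
Background subtraction (median of unlabeled pixels per channel) is off by
default since the upstream protocol does not mention it. Groups are
compared with a two-sided two-sample t-test; the pooled-variance Student
form is the default reading of an unqualified "t-test", with Welch
available by flag. Without background subtraction the ratio is invariant
under common rescaling of both channels.

## MALDI lipid spectra

Spectra are (m/z, intensity) profiles in negative-ion mode. The module is
range-agnostic: the analysis regions span m/z 600–1500 even though typical
acquisition windows may differ. Processing steps:

* **TIC normalization** scales each spectrum to unit total ion count —
  idempotent and scale-invariant by construction.
* **Averaging** interpolates spectra linearly onto a common grid and takes
  the pointwise mean. Statistics across biological replicates use
  replicate-averaged spectra (`averageReplicates()`), while per-spectrum
  values are retained for box-plot style summaries — both granularities
  are emitted because hundreds of pixel spectra underlie each replicate.
* **Region scheme**: Region 1 (600–825, mixed phosphatides), Region 2
  (825–950, phosphatidylinositols), Region 3 (1300–1500, cardiolipins —
  exclusive to mitochondrial membranes). Boundaries are half-open
  `[lower, upper)`: 825 falls in Region 2, 950 in none, 1300 in Region 3.
  Region intensity is the trapezoidal integral over the region's grid
  points.
* **Peak extraction** takes the windowed *maximum* within ±0.2 Da of the
  target by default, matching the "peak intensity" convention of MALDI
  box plots; a trapezoidal integral mode is available by flag. The 0.2 Da
  default follows from the instrument class: resolving power ≈ 5000 at
  m/z 885.56 implies a FWHM near 0.18 Da.
* **Annotation** matches the diagnostic species CerP (d16:1/18:0) at
  616.47, PG (18:1/18:1) at 773, SM (d18:1/24:1) at 797.67 and
  PG (18:1/22:6) at 819 within the same tolerance; unmatched peaks in
  1300–1500 are annotated at class level as cardiolipin.

Per-peak group comparisons use two-sided Mann–Whitney U tests on
TIC-normalized per-spectrum intensities, with the direction reported as
the sign of the median difference versus control.

## pLSA over binned spectra

For unsupervised discrimination, TIC-normalized spectra are summed into
1 Da m/z bins (the default trades resolution against sparsity; the peak
FWHM is far below 1 Da, so each lipid lands in at most two bins) to form a
document–term matrix of spectra × bins. Probabilistic latent semantic
analysis factorizes $P(d, w) = \sum_z P(z \mid d)\, P(w \mid z)$ by plain
EM — no tempering or annealing. The E-step posterior
$P(z \mid d, w) \propto P(z \mid d) P(w \mid z)$ and the M-step
reestimates both distributions from posterior-weighted counts.
Implementation choices:

* Continuous nonnegative weights are used directly — the EM updates only
  require nonnegativity, and TIC-normalized intensities are fractional.
  Rows of the matrix sum to 1, so every document carries equal weight.
* Initialization draws both distributions from symmetric Dirichlet(1)
  under the stated seed; 5 restarts (seeds `seed`, `seed+1`, …) keep the
  best final log-likelihood. All randomness flows through these seeds.
* Convergence: relative log-likelihood change below `1e-6`, capped at 500
  iterations. The trace is monotone up to `1e-10` slack, and both
  distributions renormalize to within `1e-9` every iteration — both are
  validity conditions of the returned model object.
* Group labels are never read by the fit; they enter only in
  `discriminateTopics()`, which assigns documents to nearest class
  centroids in topic space and reports accuracy and mean silhouette
  width. Topic permutation ambiguity is handled in tests by matching
  dominant topics per class. The commercial software that popularized
  pLSA for MALDI imaging does not document its exact variant, so group
  discrimination is reproduced qualitatively, never numerically.

Degenerate cases are reported, not guessed: a K = 1 model has identical
loadings for all documents (silhouette undefined), and a single-class
labeling has undefined accuracy.

## Statistical kernels

The shared Mann–Whitney kernel uses the exact null distribution when
$n_x + n_y \le 20$ and there are no ties (two-sided p = twice the smaller
tail, capped at 1), and otherwise the normal approximation with midrank
tie correction and continuity correction; the method used is recorded in
every result row. Ties always route to the approximation. The t kernel
offers Student and Welch variants. Percentages in the differential
expression count summaries round half-up to integers, which is how the
printed splits 57/43 and 63/37 arise, and no multiple-testing correction
is applied by default (the imaging analyses report raw per-comparison
p-values); a Benjamini–Hochberg helper is provided but off by default.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions for every test:

* **TPEF fields**: non-overlapping elliptical cells (matching the
  enlarged, flat senescent morphology and keeping masks unambiguous),
  each containing a mixture of punctate Gaussian spots (weight =
  `aggregation`) and a uniform dispersed component at *fixed total
  intensity per cell* — so aggregated and dispersed cells differ only in
  spatial arrangement, and the AI ordering is forced by construction.
  Acquisition artifacts are layered in the order the preprocessing
  expects to undo them: additive Gaussian detector noise, then the
  circular row shift, then 1-pixel outliers (so outlier removal is
  exercised *before* deskewing). Bright outliers can land anywhere; dark
  dropouts only where the local neighborhood is signal-bearing and
  locally smooth, because a zero pixel inside an already-dark or steep
  region is not a well-defined 1-pixel outlier — positions failing that
  rule receive a bright outlier instead. Defaults: 256×256 px, 20 cells,
  6 spots of σ = 2 px per cell, background σ = 0.02 a.u., 5 outliers,
  row shift 2.
* **JC-1 pairs**: constant per-cell green levels (0.8–1.2 a.u.) with red
  = ratio × green, ratios drawn from truncated normals (defaults:
  polarized mean 2.0, depolarized 0.8, σ = 0.3, 50 cells per group — the
  cell count used for two of the three measured lines).
* **Spectra**: sums of Gaussian peaks at 14 negative-ion lipid positions
  (including all four annotated diagnostic species and three
  cardiolipins), scaled by per-region group effects (defaults: both
  senescence inducers double Region 3; Regions 1–2 move oppositely for
  the two inducers, all effects ≥ 1.5-fold), a per-spectrum TIC jitter
  (0.8–1.25) and pointwise multiplicative log-normal noise with CV 0.1 —
  the standard MS noise approximation. Grid 600–1500 Da at 0.1 Da,
  FWHM 0.18 Da, 20 spectra per group cycling over 3 replicates.

None of this is a physical model: there is no two-photon PSF, no
photobleaching, no isotope patterns, no peak drift or baseline, and cell
shapes are ideal ellipses. Passing tests therefore demonstrate that the
*algorithms* recover known ground truth under controlled artifacts — they
do not certify performance on real microscopy or MS data, where
segmentation quality, calibration of the a.u. scale, and mass alignment
dominate.

## Numerical choices and problem sizes

Determinism is absolute: every generator and the pLSA fit consume a
single integer seed through one RNG scope that restores the caller's RNG
state. Test and verification workloads were sized to keep the full suite
in the low minutes on a single core while leaving no behavior untested:
20-seed replications for the AI-recovery and pLSA-discrimination
experiments (20 cells/group and 20 spectra/group respectively), 50 random
matrices for EM monotonicity, exhaustive Mann–Whitney enumeration for all
tie-free sample pairs with $n_x + n_y \le 10$, and 1000 Monte-Carlo
replicates for type-I calibration.

## Known limitations

* The segmentation convenience function (Otsu + connected components) is
  a fallback; the quantitative claims assume curated label masks.
* The serpentine model is a single global integer shift; sub-pixel or
  row-varying lags are out of scope.
* The a.u. calibration of the 0.25 threshold is instrument-specific and
  must be supplied by the user for real data.
* imzML ingestion is not implemented; CSV + manifest is the canonical
  interchange format for spectra.
* pLSA restarts mitigate but cannot eliminate local optima; the
  likelihood trace and seed are stored in the model for auditability.
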