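# senometrix

Quantitative profiling of therapy-induced senescent cancer cells from
label-free microscopy and MALDI lipid mass spectrometry.

Cancer cells surviving chemotherapy (e.g. doxorubicin) or irradiation can
enter senescence — a stable arrest with profound mitochondrial remodeling.
`senometrix` implements three complementary readouts of that state, plus
deterministic synthetic-data generators so every stage is testable against
known ground truth:

* **TPEF imaging.** Two-photon excited autofluorescence of the metabolic
  cofactors NAD(P)H and FAD is preprocessed (1-pixel cosmic-ray outlier
  removal, serpentine raster deskew by circular row shifts, absolute
  0.25 a.u. thresholding) and summarized per cell by the mitochondrial
  **Aggregation Index**

  $$\mathrm{AI} = \frac{\text{Max TPEF [a.u.]}}
  {[\text{Area}_\mathrm{TPEF}/\text{Area}_\mathrm{Cell}]\,\%},$$

  where Max TPEF is the mean of the top 10% of pixel values in the cell.
  Dispersal of the cofactor signal through the cytosol — the senescent
  phenotype — lowers the AI. Groups are compared by two-sided
  Mann–Whitney U tests.
* **JC-1 ratiometry.** Per-cell red/green mean-intensity ratios of the
  membrane-potential dye JC-1 (ratio drops with mitochondrial
  depolarization), compared by two-sample t-tests.
* **MALDI lipidomics.** TIC normalization, replicate averaging, a
  three-region m/z scheme (600–825 mixed phosphatides / 825–950 PI /
  1300–1500 cardiolipin), extraction and annotation of the diagnostic
  peaks (CerP at m/z 616.47, PG at 773 and 819, SM at 797.67), per-peak
  group tests, and unsupervised discrimination of treatment groups by a
  from-scratch **pLSA** (EM) fit over binned spectra.

See `vignettes/senescence-profiling.Rmd` for the full account of models,
parameters and design decisions.

## Worked example

Two simulated fields of view — control cells with tightly aggregated
cofactor signal versus senescent-like cells with dispersed signal at the
same total intensity — through the full TPEF pipeline:

```r
library(senometrix)

simCtrl <- simulateTpefImage(tpefSimConfig(aggregation = 1.0, seed = 1))
simSen  <- simulateTpefImage(tpefSimConfig(aggregation = 0.2, seed = 2))
res <- runTpefPipeline(
  list(channelMatrix(simCtrl$image), channelMatrix(simSen$image)),
  list(simCtrl$mask, simSen$mask),
  groups = c("control", "senescent"))

aggregate(cbind(aggregation_index, area_fraction_pct) ~ group,
          res$records, median)
#>       group aggregation_index area_fraction_pct
#> 1   control       0.027700823          55.94093
#> 2 senescent       0.008259337         100.00000

res$comparisons[, c("metric", "group_a", "group_b", "p_value")]
#>              metric group_a   group_b      p_value
#> 1 aggregation_index control senescent 6.795615e-08
#> 2 area_fraction_pct control senescent 3.995359e-08
```

The senescent group spreads its signal over the whole cell (area fraction
100% vs 56%) and its median AI drops more than threefold; the
Mann–Whitney comparison is highly significant in the expected direction.

The MALDI side, on simulated three-group spectra (control, doxorubicin,
radiation) with the shipped group effects:

```r
sim <- simulateSpectra(spectraSimConfig(seed = 1))
pg <- peakGroupSummary(sim$set, peaks = c(773, 819))
pg$comparisons[, c("mz", "group_a", "group_b", "p_value", "direction")]
#>    mz     group_a group_b      p_value direction
#> 1 773 doxorubicin control 4.680403e-05        up
#> 2 773   radiation control 6.795615e-08      down
#> 3 819 doxorubicin control 5.115262e-03        up
#> 4 819   radiation control 6.795615e-08      down

annotateLipid(773)
#>    mz       species class
#> 2 773 PG(18:1/18:1)    PG

dtm <- binSpectra(sim$set, binWidth = 1.0)
fit <- plsaFit(dtm, K = 3, seed = 7)
fit
#> PLSAModel: K=3, 60 docs x 22 terms, 112 EM iterations (converged),
#>   logLik -165.0137
discriminateTopics(fit, attr(dtm, "groups"))$accuracy
#> [1] 1
```

The recovered peak directions follow the injected per-region effects, and
the three treatment groups separate perfectly in pLSA topic space.

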