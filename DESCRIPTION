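Package: senometrix
Title: Quantitative Profiling of Therapy-Induced Senescent Cancer Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image and mass-spectrometry analytics for therapy-induced
    senescence in cancer cells. Implements the label-free two-photon excited
    fluorescence (TPEF) preprocessing recipe (1-pixel cosmic-ray outlier
    removal, serpentine raster deskew by circular row shifts, absolute
    0.25 a.u. thresholding) and the mitochondrial Aggregation Index; per-cell
    JC-1 red/green mitochondrial membrane-potential ratiometry; MALDI-TOF
    lipid-spectrum preprocessing (TIC normalization, replicate averaging,
    three-region scheme, peak extraction and lipid annotation); a from-scratch
    probabilistic latent semantic analysis (pLSA) fitted by EM over binned
    spectra for group discrimination; shared Mann-Whitney U and t-test
    kernels; and deterministic synthetic-data generators that emulate the
    acquisition artifacts so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
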