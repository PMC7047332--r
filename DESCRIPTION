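Package: irwall
Title: Cell-Wall Profiling from ATR-FTIR Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for attenuated-total-reflectance Fourier-transform
    infrared (ATR-FTIR) hyperspectral images of plant tissue sections. Provides
    spectral preprocessing (standard normal variate and polynomial detrending),
    reading and writing of hyperspectral absorbance cubes (ENVI-style, long-table
    and native formats), pixel assignment to cell-wall classes by Spearman
    correlation against mean representative spectra, detection of differentially
    absorbed wavenumbers between classes with pairwise Wilcoxon rank-sum tests and
    Bonferroni correction, annotation of detected wavenumbers with cell-wall
    compound classes, reporting utilities (class-average spectra, PCA loadings,
    column-scaled heatmap matrices with correlation-distance dendrograms,
    single-wavenumber absorbance images, score-plot ellipses), and a synthetic
    scene generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    png
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
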