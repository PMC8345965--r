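Package: hdlstab
Title: Fluorescence-Based Analytics for an HDL Stability Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a tryptophan-fluorescence assay of
    high-density lipoprotein (HDL) stability under chemical denaturation.
    Reads emission-spectrum time series, computes the ratio of fluorescence
    intensities rfi = (Em344 + Em365)/Em330, normalizes denaturation time
    courses to percent denaturation using 0 h / 26 h anchors, fits anchored
    logistic kinetics to estimate the 50% denaturation time (DT50), scores
    samples at a fixed 8 h incubation time, quantifies detached-protein
    fractions from native-PAGE densitograms by area-under-curve integration,
    and implements the case-control statistical layer (assay CVs, normality-
    gated group comparisons, Spearman and partial correlations, lipid-
    composition ratios, HDL-cholesterol matching, and recursive-feature-
    elimination logistic classification). Includes calibrated synthetic
    generators for spectra, denaturation kinetics, densitograms, and cohorts
    so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
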