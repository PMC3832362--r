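Package: sicklemetry
Title: Red Blood Cell Sickling Morphometry, Gating and Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of red blood cell sickling from imaging
    cytometry and time-lapse video microscopy. Provides a ground-truthed
    synthetic generator for single-cell image events and sickling videos,
    single-cell morphometry (mask, axis and thickness metrics, boundary
    Fourier symmetry, co-occurrence texture), a sequential gating chain that
    isolates mature enucleated marker-positive red cells, Fisher's-discriminant
    metric ranking with a Sickle Score classifier and spillover-calibrated
    gate, and survival-style sickling kinetics (percent sickled, median time,
    delay time, maximum rate) with Gehan-Breslow-Wilcoxon and rank-sum group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
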