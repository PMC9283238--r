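Package: bonequal
Title: Colocalized Bone-Quality Analysis from Raman Spectroscopy,
    Nanoindentation, and Quantitative Backscatter Electron Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for colocalized bone-quality measurements:
    Raman band-ratio compositional parameters (mineral-to-matrix ratio,
    type B carbonate substitution, crystallinity) from raw spectra via
    polynomial baseline correction, cosmic-ray removal and Savitzky-Golay
    smoothing; Oliver-Pharr nanoindentation analysis (reduced elastic
    modulus and hardness) from load-displacement records; calibrated
    backscatter-electron bone mineral density distributions (CaMean,
    CaPeak, CaWidth); and the two statistical layers used in skeletal
    phenotyping studies - per-specimen group comparisons (Shapiro-Wilk
    gate, one-way ANOVA with Tukey HSD, Kruskal-Wallis) and pooled
    perilacunar distribution-shift testing by two-sample Kolmogorov-Smirnov
    and Anderson-Darling tests with Bonferroni correction. A synthetic-data
    module generates spectra, indentation curves, backscatter images and
    full three-group study datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
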