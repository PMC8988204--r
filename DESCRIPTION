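Package: cropmtl
Title: Multitask Deep Learning for Wheat Yield and Grain Protein Content
    from Time-Series Canopy Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous prediction of wheat grain yield and grain protein
    content (GPC) from near-daily time series of canopy structural and
    spectral traits observed by proximal sensing. Provides a synthetic
    field-trial generator emulating a 480-plot split-plot nitrogen
    experiment, extraction of four spectral indices (GNDVI, CVI, NCPI,
    MCARI) and four structural traits (Hmean, H99, PLA, Volume) from fused
    LiDAR+multispectral point clouds, dataset preparation (vectorization,
    linear interpolation of missing days, jitter/scale/resample
    augmentation, min-max normalization), four single- and multitask
    fusion network topologies with five interchangeable time-series
    feature extractors trained under a weighted mean-absolute-error loss,
    evaluation metrics (R-squared, RMSE, rRMSE), and attention-based daily
    feature-importance profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
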