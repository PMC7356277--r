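Package: potatoRUE
Title: Radiation Interception, Conversion and Partitioning Efficiency
    Analysis for Potato Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate radiation interception (epsilon_i), conversion
    (epsilon_c) and partitioning (epsilon_p) efficiencies of potato accessions
    from multispectral canopy time series and daily weather. Includes
    SAVI-threshold canopy segmentation and NDVI extraction, Beta canopy-growth
    fitting on thermal time, a radiation-driven tuber growth model with
    Gompertz partitioning (yielding biomass, harvest index and tuberization
    precocity), senescence-delay slope extraction, augmented-block-design
    ANOVA with Federer-adjusted means, and multivariate characterization
    (correlations, PCA, Ward clustering, regression of yield on principal
    components). A synthetic field-trial generator emulating a Lima winter
    growing season makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
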