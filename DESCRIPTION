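Package: bilat
Title: Bilateral Asymmetry, Emergence Production and Hydrological
    Correlates for Stream Insects
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies developmental instability and aquatic-terrestrial
    energy export for stream insect populations. Provides the fluctuating-
    asymmetry index suite (FA1, FA4a, FA10a) with measurement-error
    partitioning from replicated bilateral trait measurements via balanced
    two-way mixed-model ANOVA, together with Shapiro-Wilk antisymmetry and
    one-sample t directional-asymmetry screens; benthic and emergence
    biomass accounting from length-mass allometry, production-to-biomass
    (P/B) secondary production and the emergence-to-production (E/P) export
    ratio; trailing-window precipitation summaries and rank correlations of
    adult body size against hydrology; and AICc forward model selection
    with pairwise-correlation and variance-inflation-factor screening. A
    synthetic-data module generates every input the pipeline consumes with
    the statistical structure the analyses assume, so the whole workflow is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
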