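Package: soilcue
Title: Soil Microbial Growth, Respiration and Carbon Use Efficiency from
    18O-Water Labelling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts raw instrument readings from 18O-water DNA
    stable-isotope probing assays (IRMS isotope ratios, fluorometric DNA
    quantification, gas-chromatography headspace CO2, chloroform
    fumigation-extraction organic carbon) into microbial growth,
    respiration, carbon uptake and carbon use efficiency per gram soil
    dry mass, and analyses them over a multifactorial warming x CO2 x
    drought surface-response field design across a growing season.
    Includes a forward simulator of the full study (latent treatment
    response surfaces through instrument-level noise), per-date
    second-order response-surface regression with marginality-based model
    reduction, an iterative feasible generalised least squares estimator
    with per-date variances and optional within-plot correlation, a
    two-way drought ANOVA with Tukey HSD post-hoc letters, and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    nlme,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
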