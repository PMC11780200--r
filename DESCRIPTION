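Package: pollscape
Title: Landscape-Scale Pollinator Populations from Transect Counts and
    Habitat Quality-Quantity Trade-Offs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates landscape-scale wild bee and hoverfly population
    sizes from standardized transect counts in seminatural habitats, and
    locates the seminatural-habitat cover threshold above which improving
    habitat quality (flower availability) boosts populations more than
    adding habitat area.  Fits Gaussian linear mixed models with crossed
    landscape and sampling-round random intercepts on log-transformed
    densities, performs likelihood-ratio model selection, extrapolates
    fitted densities over a habitat quantity-by-quality prediction grid
    to population surfaces, and computes quality:quantity response-ratio
    curves with break-even thresholds under 1:1, 2:1 and 3:1 step ratios.
    Includes a synthetic survey-data generator with known ground truth
    for parameter-recovery testing of the whole chain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
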