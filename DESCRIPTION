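Package: polypdemog
Title: Growth and Population Dynamics of Solitary Corals Along
    Temperature Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Age-based growth and demographic analysis of solitary
    scleractinian corals surveyed along a sea surface temperature (SST)
    gradient. Estimates von Bertalanffy growth parameters from
    band-dated skeletons by the Ford-Walford plot method, gates pooling
    of growth curves across sites with an ANCOVA homogeneity test,
    assigns ages to whole survey populations by inverting the growth
    curve, estimates instantaneous mortality (Z) and population
    structure stability from semi-log age-frequency regressions, builds
    observed and theoretical age and biomass structures, and correlates
    all demographic parameters with site temperature using Pearson
    coefficients with bootstrap resampling. Includes an
    individual-based simulator of coral populations, band-dated
    subsamples and temperature series so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
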