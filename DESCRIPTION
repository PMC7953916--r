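Package: regenscore
Title: Practice-Based Scoring and Outcome Validation for Regenerative
    Cropland and Rangeland
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to score farming operations on practice-based
    regenerative matrices for cropland (nine binary items) and rangeland
    (four ordinal items), locate the natural break that separates
    regenerative from conventional score clusters, compute the soil
    (loss-on-ignition organic matter, fine particulate organic matter,
    bulk density, single-ring infiltration, Haney soil health score,
    equivalent-soil-mass carbon and nitrogen stocks) and community
    (Shannon and Gini-Simpson diversity, richness, trophic-guild
    abundance, disc-pasture biomass index) response metrics, and fit the
    score-versus-outcome regression and mixed-model validation suite. A
    seeded synthetic farm-data generator reproduces the statistical
    structure the validation assumes (bimodal practice adoption, linear
    score effects with a clay covariate, farm random effects,
    score-proportional variance inflation) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
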