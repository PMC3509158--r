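Package: fallowfun
Title: Plant Diversity and Ecosystem-Service Multifunctionality in Smallholder Fallows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whether plant diversity or environmental
    favorability better predicts ecosystem-service multifunctionality in
    smallholder fallow fields. Converts vegetation survey records into
    standing wood and forage biomass (general humid-region allometry plus
    biovolume conversion), fits the Horton equation to ring-infiltrometer
    time series to estimate steady infiltration rates, aggregates soil base
    cations, computes abundance-filtered species richness, community-weighted
    trait means and UPGMA dendrogram functional diversity, derives two
    multifunctionality indicators (proportion of functions above threshold
    maxima and mean percentage excess above function means) with pairwise
    jointness, and compares univariate and additive bivariate linear models
    of the indicators on diversity and environmental predictors. A seeded
    synthetic-data generator emulating grazed and improved (planted
    woody-legume) fallows makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
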