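Package: mycocontext
Title: Context Dependency of Root-Associated Fungal Community Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for testing whether the abiotic and biotic
    drivers of root-associated fungal diversity and community composition are
    context specific. Provides negative-binomial GLMs of OTU richness at
    nested spatial scales (site, region, all data pooled) with AIC and
    adjusted D-squared comparison of abiotic versus biotic variable sets,
    cross-site model transfer quantified by predictive root-mean-square error
    with a within/between-region ANOVA, per-OTU abundance models with
    library-size offsets and delta-AIC support classification, a finite
    mixture of negative-binomial regressions (species archetype model /
    ecogroups) fitted by EM, a permutation chi-squared test of association
    between ecogroups and fungal trophic guilds, and a seeded synthetic-data
    generator that emulates the sampling design these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    withr
Config/testthat/edition: 3
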