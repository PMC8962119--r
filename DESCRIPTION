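Package: orchardgt
Title: Genetic Testing in Seed-Orchard Plantations by Pedigree
    Reconstruction and Spatial Animal Models
Version: 0.1.0
Authors@R:
    person("Orchard", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic testing of plantations raised from
    seed-orchard crops when no progeny trial exists.  Covers
    microsatellite diversity statistics (allele counts, effective
    alleles, observed and expected heterozygosity, fixation index,
    polymorphic information content, non-exclusion probabilities),
    likelihood-based maternity assignment with a genotyping-error model
    and Monte-Carlo confidence tiers, pedigree-derived additive
    relationship matrices, restricted maximum likelihood fitting of
    individual-tree (animal) mixed models with spatially correlated
    residuals (including separable row-by-column first-order
    autoregression), AICc model comparison, heritability estimation,
    best linear unbiased prediction of breeding values, Moran's I
    spatial autocorrelation tests, and a fully seeded synthetic
    seed-orchard simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
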