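Package: mgidi
Title: Multitrait Genotype-Ideotype Distance Selection for Replicated Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the complete multitrait evaluation of genotypes in
    randomized complete block trials: per-trait ANOVA with expected-mean-square
    variance components, broad-sense heritability and genotypic/phenotypic
    coefficients of variation; correlation, principal component and path
    analysis of genotype means; Gower-dissimilarity hierarchical clustering
    with silhouette-guided cluster number selection; and the multitrait
    genotype-ideotype distance index (MGIDI) with factor analysis, varimax
    rotation, predicted selection gains and per-factor strength/weakness
    profiles. Includes a synthetic trial simulator with known genetic
    architecture for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
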