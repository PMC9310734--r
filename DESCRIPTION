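Package: landpop
Title: Landscape Population Genomics from Genotype Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of population-genetic summary statistics computed
    directly on genotype likelihoods of low-coverage biallelic data (site
    frequency spectra by EM, nucleotide diversity, individual
    heterozygosity, inbreeding coefficients, pairwise genetic distances,
    genotype-posterior covariance PCA, two-dimensional site frequency
    spectra and Hudson FST), together with a landscape-genetics framework
    linking genetic differentiation to geography: ecological niche
    suitability models with AUC/TSS and spatial-block cross-validation,
    multivariate environmental similarity surfaces, terrain-ruggedness and
    habitat resistance surfaces, least-cost distances on a 16-direction
    geodesic transition graph, and matrix inference by Mantel permutation
    tests, multiple matrix regression with randomization, and generalized
    dissimilarity modelling with monotone I-splines and permutation-based
    backward elimination. A seeded synthetic-data module generates
    landscapes, occurrences, locality layouts and genotype likelihoods with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    igraph,
    glmnet,
    pracma,
    jsonlite,
    data.table,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
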