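Package: inbredload
Title: Pedigree Decomposition and Genomic Analysis of the Inbreeding Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and map the inbreeding load in pedigreed
    livestock populations. Decomposes each animal's inbreeding coefficient
    into per-ancestor partial coefficients by Mendelian partitioning
    (validated against a gene-dropping Monte Carlo oracle), builds pedigree
    (A-inverse), genomic (VanRaden G) and single-step (H-inverse)
    relationship matrices, fits a bivariate Bayesian animal model for
    additive effects and ancestral inbreeding loads by Gibbs sampling under
    a Kronecker V x H prior, back-solves GBLUP solutions into SNP effects,
    and scans the genome for windows carrying additive or inbreeding-load
    variance. Includes a synthetic-data generator (pedigree, gene-dropped
    genotypes, phenotypes) with the exact model structure used by the
    estimator, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
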