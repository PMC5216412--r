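Package: refugium
Title: Dating Post-Glacial Population Expansions from Y-STR and Autosomal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and date population expansions from glacial
    refugia using Y-chromosome short tandem repeat (STR) haplotypes and
    autosomal SNP data. Implements a Bayesian Markov chain Monte Carlo sampler
    for times to the most recent common ancestor (TMRCA) and population split
    times under the single-step mutation model with a constant-then-exponential
    growth, splitting demography; hierarchical analysis of molecular variance
    (AMOVA) with Phi statistics; Slatkin-style R_ST and Hudson F_ST distances;
    classical multidimensional scaling, Mantel and Fisher exact geographic
    concordance tests; neighbor-joining and Ward clustering; median-joining
    haplotype networks; F_ST-based divergence dating with harmonic-mean
    effective population sizes; and a structured-coalescent simulator that
    generates STR haplotype and SNP genotype tables with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
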