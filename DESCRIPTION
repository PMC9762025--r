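Package: microsem
Title: Recursive Structural Equation Models for Microbiome-Mediated Host Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian analysis of the causal effect of individual gut-microbiome
    features (OTU abundances) on growth traits via a three-trait recursive
    structural equation model fitted by Gibbs sampling, with litter, cage and
    genomic random effects and a genomic relationship matrix. Separates direct
    host-genetic effects from microbiota-mediated genetic effects through the
    reduced-model (multiple-trait animal model) transformation of the covariance
    matrices, and reports total/direct/indirect genetic variances, covariances,
    heritabilities, SD-standardized structural coefficients, highest posterior
    density intervals and significance/relevance calls per OTU. Includes
    cumulative sum scaling (CSS) normalization and prevalence/abundance filtering
    of OTU count tables, SNP quality control and VanRaden genomic relationship
    matrices from PLINK files, a parameter-known synthetic population generator,
    and a per-OTU study driver with Venn and family-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    yaml,
    optparse
Config/testthat/edition: 3
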