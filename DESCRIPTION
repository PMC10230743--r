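Package: dyadtrans
Title: Dyadic Models of Maternal and Social Gut-Microbiota Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating vertical (maternal) from horizontal (social)
    transmission signals in host-associated microbiota using dyadic data.
    Builds pairwise microbiota similarity (Jaccard, Bray-Curtis) from ASV
    tables, social association (adjusted Simple Ratio Index) from nightly
    logger co-detections, and kinship covariates from a pedigree; fits a
    Bayesian Beta regression with two multi-membership random intercepts
    (individuals and samples in each dyad) by Hamiltonian Monte Carlo;
    attributes the maternal signal to bacterial families by a
    leave-one-family-out scan; and includes a Mantel permutation test and a
    synthetic-study generator with planted transmission effects for
    end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    vegan,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr,
    rjags
Config/testthat/edition: 3
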