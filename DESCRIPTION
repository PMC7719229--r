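Package: nhejphylo
Title: Comparative Genomics and Phylogenetics of Bacterial Non-Homologous End Joining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of bacterial genomes into non-homologous end joining
    (NHEJ) repair states from Ku/LigD protein-domain evidence, ancestral-state
    reconstruction of NHEJ evolution with a continuous-time Markov (Mk) engine
    (ER/SYM/ARD fits, MCMC over the rate matrix, stochastic character mapping by
    uniformization, gain/loss accounting), and phylogenetically controlled tests
    of association between NHEJ and genome size or growth rate (Pagel's lambda,
    Blomberg's K, phylogenetic ANOVA, Pagel's correlated-evolution test,
    phylogenetic logistic regression, Mantel and gene-pool randomization nulls).
    Includes a fully seeded synthetic-data generator that emulates every input the
    pipeline consumes, so each stage is testable end-to-end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    vegan,
    car
Config/testthat/edition: 3
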