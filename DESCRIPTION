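Package: notosex
Title: Species Delimitation and Sexual-System Evolution in Tadpole Shrimps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetics toolkit for studying the lability of
    sexual systems (gonochorism versus androdioecy) in Notostraca and similar
    crustacean groups. Implements single-threshold generalized mixed
    Yule-coalescent (GMYC) species delimitation on ultrametric barcode trees,
    supermatrix concatenation with partition and missing-data bookkeeping,
    uncorrected between-cluster p-distances, rule-based classification of
    populations and taxonomic units into sexual systems from sex-ratio,
    reproduction-in-isolation and ovotestis evidence, unordered
    maximum-parsimony ancestral-state reconstruction with polymorphic and
    uncertain tips and minimum origin counting, two-state Markov (Mk)
    likelihood mapping with four transition-rate models compared by likelihood
    ratio tests and marginal ancestral reconstruction, and a lambda-scaled
    phylogenetic generalized least squares t-test of latitude against sexual
    system. Ships seed-deterministic simulators (Yule species trees,
    within-species coalescents, Mk characters, lambda-Brownian traits and full
    synthetic study bundles) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils
Suggests:
    nlme,
    phangorn,
    phytools,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
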