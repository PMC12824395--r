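Package: medseq
Title: State Sequence Analysis of Medication-Use Trajectories in Incident Bipolar Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing three-year medication-use state
    sequences from pharmacy dispensing registers, motivated by treatment of
    incident bipolar disorder. Converts dispensing records into continuous
    drug-use periods, applies incidence/washout/residency eligibility rules,
    assigns one of seven mutually exclusive treatment states to each of twelve
    91-day periods, and analyses the resulting sequences with optimal-matching
    dissimilarities under transition-rate (TRATE) substitution costs, weighted
    Ward/PAM/hybrid clustering with silhouette-based model selection,
    initiation/discontinuation trajectory classification, and multinomial
    logistic regression with marginally standardized fitted probabilities.
    Includes a synthetic registry generator with known latent typologies so the
    whole pipeline is testable without access to confidential register data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nnet,
    sandwich,
    lmtest,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
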