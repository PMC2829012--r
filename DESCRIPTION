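Package: tagbayes
Title: Bias-Corrected Bayesian Inference for SAGE and DGE Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference for mRNA population proportions from tag-count
    transcriptome libraries (SAGE and DGE tag profiling) under incomplete
    restriction-enzyme digestion.  Models per-gene tag formation
    probabilities with a geometric site-cleavage model, provides a
    bias-corrected maximum likelihood estimator, and implements three
    hierarchical Gibbs samplers (Dirichlet-Poisson-Binomial,
    Dirichlet-Multinomial-Binomial, and a missing-data augmentation) that
    embed the tag-formation model in the likelihood.  Includes a
    credible-interval coverage simulation study, autocorrelation
    diagnostics, and odds-ratio based differential-expression tests that
    account for tag-formation bias across libraries with different
    cleavage probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
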