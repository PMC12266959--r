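Package: scrdan
Title: Robust Domain-Adversarial Cell Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transfers cell-type labels from a labeled reference (source)
    single-cell RNA-seq dataset to an unlabeled query (target) dataset in the
    presence of batch effects. The core is a denoising domain-adversarial
    network: a shared encoder and decoder reconstruct expression profiles in
    both domains, a domain discriminator trained through a gradient reversal
    layer aligns the two latent distributions, a batch-hard triplet loss keeps
    cell types compact and separated, and consistency plus virtual adversarial
    regularization harden the embedding against noise. Includes a Splat-style
    two-batch count simulator with a tunable batch-effect intensity knob,
    preprocessing (CPM/TPM, log-normalization, highly variable gene selection,
    cross-species homolog mapping), evaluation metrics (mean per-class
    accuracy, silhouette score), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
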