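Package: tfvae
Title: Transcription-Factor-Anchored Variational Autoencoders for In Silico Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a variational autoencoder whose latent space is anchored to
    measured transcription-factor (TF) expression, so that editing latent TF
    values and decoding yields predicted whole transcriptomes. Provides
    quantile-based in silico TF perturbation, correlation-based assessment of
    perturbation success (Ideal / Under / N.S. labels from t-statistics),
    signed TF-regulatory-network expansion of perturbation candidates via
    shortest-path sign propagation, combinatorial screening of TF duos, and a
    synthetic single-cell lineage simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
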