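Package: attnddg
Title: Sequence-Only Prediction of Antibody-Antigen Binding Affinity
    Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts changes in antibody-antigen binding free energy
    (ddG, kcal/mol) upon mutation from sequence alone.  Frozen
    per-residue embeddings of the wild-type and mutant antibody and
    antigen sequences are refined by a convolution-gated,
    rotary-position-embedded dual multi-head cross-attention module,
    pooled to complex-level vectors and regressed to ddG with a small
    fully connected head.  Includes parsers for AB-bind/SKEMPI-style
    mutation tables, a deterministic mock embedder for offline work,
    k-fold, sequence-identity and mutation-depth evaluation splits, an
    attention-ablation harness, attention-weight interpretability
    reports, and a synthetic-data generator with a known additive plus
    interaction ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
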