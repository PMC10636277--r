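Package: tcrtyper
Title: Multi-Class T-Cell Receptor Epitope Specificity Classification with
    Transformer Heads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies T-cell receptor (TCR) beta-chain CDR3 sequences into
    epitope specificity classes in a multi-class setting. Provides the VDJdb
    preprocessing cascade (confidence-score, host-species, epitope-species and
    chain filters with per-step accounting, deduplication, composite class
    labels, stratified splits, ordinal gene vocabularies), amino-acid
    tokenization with per-position V/J gene feature alignment, a compact
    trainable transformer encoder with three interchangeable classification
    settings (sequence-only linear head, bilinear fusion of pooled output with
    gene ordinals, and gene embeddings injected at the embedding layer),
    multi-class focal loss, a fine-tuning loop with early stopping and
    per-group learning rates, a pluggable hyperparameter-search driver, an
    evaluation suite (weighted F1, balanced accuracy, one-vs-rest AUROC,
    paired Wilcoxon model comparison, label-permutation control, V/J-only
    feed-forward control model), and a synthetic VDJdb-dialect repertoire
    generator with controllable motif and gene-usage class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
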