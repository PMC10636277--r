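# tcrtyper

Multi-class classification of T-cell receptor (TCR) epitope specificity
from TRB CDR3 amino-acid sequences and V/J gene usage.

## What problem this solves, and for whom

T cells recognize infections through the binding of their receptors to
epitopes — short peptides presented by the MHC. Predicting *which* epitope
a given receptor binds from its hypervariable CDR3 loop is a central
problem in computational immunology, complicated by enormous receptor
diversity and small, heavily imbalanced curated databases. `tcrtyper` is
for immunoinformaticians who want a complete, inspectable, CPU-scale
implementation of the transformer-head approach to this task: one receptor
in, one of C epitope classes out, where a class is the composite label
`"<epitope-species> <epitope-gene> <epitope-sequence>"`.

The package implements the full experimental loop:

* **Preprocessing** of VDJdb-dialect exports: filter cascade with per-step
  accounting (missing values → human/murine hosts → confidence score > 0 →
  non-infectious epitope-species denylist → deduplication on
  (CDR3, V, J, MHC A, MHC B) → TRB chain), composite class labels, a
  minimum class size of 50, easy/hard class categorization (>100 instances
  is easy), stratified 70/15/15 splits with a per-class floor rule, and
  ordinal gene vocabularies (n genes → embedding table size n + 2 for the
  padding and unknown slots).
* **Tokenization**: one token per amino acid, `[CLS] residues [SEP] [PAD]…`
  layout, attention masks, and V/J feature ids broadcast over residue
  positions only.
* **Model**: a compact trainable transformer encoder with three
  interchangeable classification settings —

  | setting | gene information | head |
  |---|---|---|
  | baseline | none | linear, `y = xAᵀ + b` |
  | classification | raw (V, J) ordinals at the head | bilinear, `y_c = x₁ᵀ A_c x₂ + b_c` |
  | embedding | gene embedding tables added to token embeddings | linear |

  plus a V/J-only feed-forward control model (two ReLU hidden layers,
  softmax output). Gene embedding tables keep a frozen all-zero padding row
  and train at 10× the base learning rate.
* **Loss**: multi-class focal loss `FL = −(1 − p_true)^γ · ln p_true`,
  with γ tunable (γ = 0 recovers cross-entropy exactly).
* **Training**: Adam with decoupled weight decay, linear warmup/decay,
  gradient accumulation, early stopping on validation loss, per-group
  learning rates, bitwise-reproducible seeded runs; a hyperparameter-search
  driver with a built-in seeded random strategy and an ask/tell adapter for
  external Bayesian optimizers.
* **Evaluation**: weighted F1/precision/recall, balanced accuracy,
  one-vs-rest AUROC per class (Mann–Whitney midranks) with unweighted mean,
  ROC point arrays, paired Wilcoxon signed-rank model comparison (exact for
  n ≤ 25), label-permutation chance control, easy/hard difficulty report.
* **Synthetic data**: a VDJdb-dialect generator with class signal
  controllable independently in CDR3 motifs and V/J usage, plus
  contamination knobs for testing every filter step.

## Worked example

Generate a 3-class synthetic repertoire with both motif and gene-usage
signal, run the preprocessing cascade, train the embedding setting, and
evaluate:

```r
library(tcrtyper)

cfg <- synthetic_config(num_classes = 3, class_sizes = c(120, 80, 60),
                        motif_fidelity = 0.9, gene_signal = "soft",
                        gene_bias_concentration = 0.3, seed = 42)
tab <- generate(cfg)
path <- tempfile(fileext = ".tsv")
write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

fl  <- apply_filters(read_vdjdb_table(path)$records)
print(fl$report)
#> Filter cascade accounting:
#>                      step remaining
#>                       raw       260
#>            remove_missing       260
#>              host_species       260
#>          confidence_score       260
#>  epitope_species_denylist       260
#>               deduplicate       260
#>                 trb_chain       260

lab   <- min_class_size_filter(assign_class_labels(fl$records)$records, 50)
split <- stratified_split(lab, seed = 42)
v_vocab <- build_gene_vocabulary(lab, "v_gene")
j_vocab <- build_gene_vocabulary(lab, "j_gene")

spec <- tokenizer_spec(max_length = 18)
tok  <- tokenize_records(lab, spec, v_vocab, j_vocab)
part <- split$partition$partition
take <- function(p) list(examples = tok$examples[part == p],
                         labels = tok$labels[part == p])

bcfg  <- backbone_config(hidden_size = 32, layers = 2, heads = 4,
                         vocab_size = length(spec$vocab), max_length = 18)
model <- build_model(bcfg, length(tok$class_levels), "embedding",
                     v_table_size = v_vocab$table_size,
                     j_table_size = j_vocab$table_size, seed = 42)
fit <- train(model, list(train = take("train"), validation = take("validation")),
             train_config(max_epochs = 15, early_stopping_patience = 4,
                          base_lr = 1e-3, gamma = 2, seed = 42))

rep <- evaluate_model(fit$model, take("test")$examples, take("test")$labels,
                      tok$class_levels,
                      difficulty = categorize_difficulty(table(lab$class_label)))
print(rep)
#> Metrics report
#>   weighted F1: 0.9232
#>   balanced accuracy: 0.9259
#>   weighted precision: 0.9289
#>   weighted recall: 0.9231
#>   mean AUROC: 0.9755 (3 classes)
#>   AUROC easy/hard: 0.9603 / 0.9830
```

The filter report shows that a clean generated table passes the cascade
untouched (contaminated tables lose the injected rows at the matching
steps). The evaluation report reads: 92% support-weighted F1 on held-out
receptors, a mean one-vs-rest AUROC of 0.98 across the three epitope
classes, and no easy/hard gap — the class with 120 instances ("easy",
more than 100) is classified no better than the smaller ("hard") classes,
which is the intended effect of the focal loss.

A command-line front end over the same functions ships in
`inst/cli/tcrtyper.R` with `simulate`, `prepare`, `train`, `evaluate` and
`compare` subcommands.

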