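# Shared fixtures: toy record tables built in code, a tiny model builder,
# and independent oracles (brute-force Wilcoxon, finite differences).

toy_records <- function(n = 3, cdr3 = NULL, chain = "TRB",
                        v_gene = "TRBV9", j_gene = "TRBJ2",
                        mhc_a = "HLA-A*02:01", mhc_b = "B2M",
                        host_species = "HomoSapiens",
                        epitope_seq = "GILGFVFTL", epitope_gene = "M",
                        epitope_species = "InfluenzaA", score = 2L) {
  if (is.null(cdr3)) cdr3 <- as.character(replicate(n, random_cdr3()))
  data.frame(
    cdr3 = rep_len(cdr3, n), chain = rep_len(chain, n),
    v_gene = rep_len(v_gene, n), j_gene = rep_len(j_gene, n),
    mhc_a = rep_len(mhc_a, n), mhc_b = rep_len(mhc_b, n),
    mhc_class = rep_len("MHCI", n),
    host_species = rep_len(host_species, n),
    epitope_seq = rep_len(epitope_seq, n),
    epitope_gene = rep_len(epitope_gene, n),
    epitope_species = rep_len(epitope_species, n),
    confidence_score = rep_len(as.integer(score), n),
    record_id = seq_len(n),
    stringsAsFactors = FALSE
  )
}

random_cdr3 <- function(len = 12) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

write_toy_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  write_vdjdb_table(records, path)
  path
}

tiny_spec <- function(max_length = 10) tokenizer_spec(max_length = max_length)

tiny_model <- function(setting = "baseline", d = 8, layers = 1, heads = 2,
                       num_classes = 3, max_length = 10, seed = 42,
                       dropout = list(attention = 0, hidden = 0,
                                      classifier = 0), ...) {
  spec <- tiny_spec(max_length)
  cfg <- backbone_config(hidden_size = d, layers = layers, heads = heads,
                         vocab_size = length(spec$vocab),
                         max_length = max_length, dropout = dropout, ...)
  build_model(cfg, num_classes = num_classes, setting = setting,
              v_table_size = 7, j_table_size = 5, seed = seed)
}

example_of <- function(cdr3 = "CASS", spec = tiny_spec(), v = 3, j = 2,
                       label = 1) {
  attach_gene_features(tokenize(cdr3, spec, label_id = label), v, j)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked |d|; mirrors the two-sided doubling rule.
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  list(statistic = v_obs, p_value = min(1, p))
}

# Central-difference gradient of the focal loss at one parameter leaf.
numeric_grad_leaf <- function(model, ex, target, gamma, path, indices,
                              eps = 1e-5) {
  loss_of <- function(m) {
    fw <- tcrtyper:::forward_example(m, ex, train = FALSE, keep_cache = FALSE)
    as.numeric(focal_loss(tcrtyper:::softmax_vec(fw$logits), target,
                          loss_config(gamma = gamma)))
  }
  vapply(indices, function(j) {
    leaf <- tcrtyper:::tree_get(model$params, path)
    m2 <- model
    leaf[j] <- leaf[j] + eps
    m2$params <- tcrtyper:::tree_set(model$params, path, leaf)
    lp <- loss_of(m2)
    leaf[j] <- leaf[j] - 2 * eps
    m2$params <- tcrtyper:::tree_set(model$params, path, leaf)
    (lp - loss_of(m2)) / (2 * eps)
  }, numeric(1))
}

# Builds the standard dissociation dataset -> tokenized splits used by the
# training-level tests.
dissociation_data <- function(num_classes = 3, class_size = 200, seed = 7,
                              max_length = 18) {
  cfg <- synthetic_config(num_classes = num_classes, class_sizes = class_size,
                          motif_fidelity = 0, gene_signal = "deterministic",
                          seed = seed)
  tab <- generate(cfg)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- assign_class_labels(apply_filters(read_vdjdb_table(path)$records)$records)$records
  split <- stratified_split(lab, seed = seed)
  vv <- build_gene_vocabulary(lab, "v_gene")
  jv <- build_gene_vocabulary(lab, "j_gene")
  spec <- tokenizer_spec(max_length = max_length)
  tok <- tokenize_records(lab, spec, vv, jv)
  part <- split$partition$partition
  mk <- function(p) list(examples = tok$examples[part == p],
                         labels = tok$labels[part == p])
  list(records = lab, spec = spec, v_vocab = vv, j_vocab = jv,
       part = part, labels = tok$labels,
       train = mk("train"), validation = mk("validation"), test = mk("test"))
}
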