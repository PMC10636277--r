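# Character-level tokenization of CDR3 amino-acid strings, with aligned
# per-position V/J gene feature ids. One token per amino acid; the layout is
# [CLS] residues [SEP] [PAD]... and gene features attach only to residue
# positions (gene id 0 everywhere else), so gene information never leaks
# into special-token or padding slots.

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[UNK]")

#' Tokenizer specification
#'
#' Fixes the token vocabulary (4 special tokens followed by the 20 canonical
#' amino acids, ids assigned by position), the padded sequence length, and
#' the backbone family the layout feeds.
#'
#' @param max_length Total padded length, including the two special tokens
#'   flanking the residues.
#' @param family `"autoencoder"` (pooled representation read from the first
#'   token) or `"autoregressive"` (read from the last non-padding token).
#' @param vocab Optional character vector overriding the token list (one
#'   token per element, id = position); must contain the four special
#'   tokens.
#' @return Object of class `tokenizer_spec`.
#' @export
tokenizer_spec <- function(max_length = 24L,
                           family = c("autoencoder", "autoregressive"),
                           vocab = c(SPECIAL_TOKENS, AMINO_ACIDS)) {
  family <- match.arg(family)
  stopifnot(all(SPECIAL_TOKENS %in% vocab), !anyDuplicated(vocab),
            max_length >= 3)
  ids <- setNames(seq_along(vocab), vocab)
  structure(
    list(vocab = vocab, ids = ids,
         pad_id = ids[["[PAD]"]], cls_id = ids[["[CLS]"]],
         sep_id = ids[["[SEP]"]], unk_id = ids[["[UNK]"]],
         special_ids = unname(ids[SPECIAL_TOKENS]),
         max_length = as.integer(max_length), family = family),
    class = "tokenizer_spec"
  )
}

#' Read / write a plain-text vocabulary file (token per line)
#'
#' Ids are assigned deterministically by line order.
#'
#' @param path File path.
#' @return Character vector of tokens.
#' @export
read_vocab_file <- function(path) readLines(path)

#' @rdname read_vocab_file
#' @param vocab Character vector of tokens.
#' @export
write_vocab_file <- function(vocab, path) {
  writeLines(vocab, path)
  invisible(path)
}

#' Tokenize a CDR3 amino-acid string
#'
#' Produces the `[CLS] residues [SEP] [PAD]...` layout with an attention
#' mask that is 1 exactly at non-padding positions. Characters outside the
#' vocabulary map to `[UNK]` and are counted in the `unk_count` field.
#' Gene feature ids are initialized to 0 (gene padding) everywhere; see
#' [attach_gene_features()].
#'
#' @param cdr3 Non-empty amino-acid string.
#' @param spec A [tokenizer_spec()].
#' @param label_id Optional integer class id carried along with the example.
#' @return Object of class `tokenized_example` with fields `token_ids`,
#'   `attention_mask`, `segment_ids`, `v_feature_ids`, `j_feature_ids`,
#'   `residue_mask`, `label_id`, `family`, `unk_count`.
#' @export
tokenize <- function(cdr3, spec, label_id = NA_integer_) {
  stopifnot(inherits(spec, "tokenizer_spec"))
  if (is.na(cdr3) || !nzchar(cdr3)) stop("empty CDR3 string", call. = FALSE)
  chars <- strsplit(cdr3, "")[[1]]
  if (length(chars) > spec$max_length - 2L) {
    stop(sprintf("CDR3 of length %d exceeds max_length %d minus specials",
                 length(chars), spec$max_length), call. = FALSE)
  }
  res_ids <- unname(spec$ids[chars])
  unk <- is.na(res_ids)
  res_ids[unk] <- spec$unk_id
  if (any(unk)) {
    warning(sprintf("%d character(s) outside the alphabet mapped to [UNK]",
                    sum(unk)), call. = FALSE)
  }
  L <- spec$max_length
  n_real <- length(res_ids) + 2L
  token_ids <- c(spec$cls_id, res_ids, spec$sep_id,
                 rep(spec$pad_id, L - n_real))
  attention_mask <- as.integer(seq_len(L) <= n_real)
  residue_mask <- as.integer(seq_len(L) >= 2L & seq_len(L) <= n_real - 1L)
  structure(
    list(token_ids = as.integer(token_ids),
         attention_mask = attention_mask,
         segment_ids = integer(L),
         v_feature_ids = integer(L),
         j_feature_ids = integer(L),
         residue_mask = residue_mask,
         label_id = as.integer(label_id),
         family = spec$family,
         unk_count = sum(unk)),
    class = "tokenized_example"
  )
}

#' Recover the CDR3 string from a tokenized example
#'
#' Inverse of [tokenize()] for strings without `[UNK]` collisions.
#'
#' @param ex A `tokenized_example`.
#' @param spec The [tokenizer_spec()] used to produce it.
#' @return Character scalar.
#' @export
detokenize <- function(ex, spec) {
  keep <- !(ex$token_ids %in% spec$special_ids)
  paste(spec$vocab[ex$token_ids[keep]], collapse = "")
}

#' Attach constant per-position V/J gene features
#'
#' Broadcasts the V and J gene ordinals over residue positions only; special
#' tokens and padding keep gene id 0 so the gene embedding's padding row
#' (frozen at zero) applies there. Idempotent.
#'
#' @param ex A `tokenized_example`.
#' @param v_ordinal,j_ordinal Positive gene ordinals (0 is reserved for
#'   padding).
#' @return The example with `v_feature_ids` / `j_feature_ids` set.
#' @export
attach_gene_features <- function(ex, v_ordinal, j_ordinal) {
  if (v_ordinal < 1 || j_ordinal < 1) {
    stop("gene ordinals must be >= 1 (0 is the reserved padding index)",
         call. = FALSE)
  }
  ex$v_feature_ids <- as.integer(ex$residue_mask * v_ordinal)
  ex$j_feature_ids <- as.integer(ex$residue_mask * j_ordinal)
  ex
}

#' Tokenize a table of labelled records
#'
#' Convenience wrapper: tokenizes every CDR3, attaches encoded V/J gene
#' ordinals, and maps class labels to integer ids over the sorted label set.
#'
#' @param records Labelled records (with `class_label`).
#' @param spec A [tokenizer_spec()].
#' @param v_vocab,j_vocab Gene vocabularies from [build_gene_vocabulary()].
#' @param class_levels Optional fixed label ordering; defaults to sorted
#'   unique labels in `records`.
#' @return List with `examples` (list of `tokenized_example`), `labels`
#'   (integer ids), `class_levels`.
#' @export
tokenize_records <- function(records, spec, v_vocab, j_vocab,
                             class_levels = sort(unique(records$class_label))) {
  label_ids <- match(records$class_label, class_levels)
  v_ord <- encode_genes(v_vocab, records$v_gene)
  j_ord <- encode_genes(j_vocab, records$j_gene)
  examples <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    ex <- tokenize(records$cdr3[i], spec, label_id = label_ids[i])
    examples[[i]] <- attach_gene_features(ex, v_ord[i], j_ord[i])
  }
  list(examples = examples, labels = label_ids, class_levels = class_levels)
}
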