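# Model checkpoints: a directory with a JSON config and the weight arrays
# in R's native serialization, plus any gene vocabularies used.

#' Save a model checkpoint
#'
#' @param model A [build_model()] result.
#' @param dir Checkpoint directory (created if missing).
#' @param v_vocab,j_vocab Optional gene vocabularies to serialize alongside.
#' @param class_levels Optional class-label ordering.
#' @export
save_model <- function(model, dir, v_vocab = NULL, j_vocab = NULL,
                       class_levels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(config = unclass(model$config), setting = model$setting,
              num_classes = model$num_classes,
              v_table_size = model$v_table_size,
              j_table_size = model$j_table_size,
              gene_lr_multiplier = model$gene_lr_multiplier,
              class_levels = class_levels)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model$params, file.path(dir, "weights.rds"))
  if (!is.null(v_vocab)) write_json_artifact(v_vocab, file.path(dir, "v_vocab.json"))
  if (!is.null(j_vocab)) write_json_artifact(j_vocab, file.path(dir, "j_vocab.json"))
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Checkpoint directory written by [save_model()].
#' @return List with `model` and (if present) `class_levels`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  bc <- cfg$config
  config <- backbone_config(
    family = bc$family, hidden_size = bc$hidden_size, layers = bc$layers,
    heads = bc$heads, vocab_size = bc$vocab_size, max_length = bc$max_length,
    pooling = bc$pooling,
    dropout = lapply(bc$dropout, as.numeric),
    scale_gene_ordinals = isTRUE(bc$scale_gene_ordinals)
  )
  model <- structure(
    list(config = config, params = readRDS(file.path(dir, "weights.rds")),
         setting = cfg$setting, num_classes = as.integer(cfg$num_classes),
         v_table_size = cfg$v_table_size, j_table_size = cfg$j_table_size,
         gene_lr_multiplier = cfg$gene_lr_multiplier %||% 10),
    class = "tcr_model"
  )
  list(model = model,
       class_levels = if (!is.null(cfg$class_levels)) {
         unlist(cfg$class_levels)
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
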