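# A compact trainable transformer encoder for CDR3 classification, with
# three interchangeable classification settings:
#   baseline       - sequence only; pooled output -> linear head
#   classification - pooled output fused with the raw (V, J) gene ordinals
#                    in a bilinear head
#   embedding      - V/J gene embedding tables added to the token embeddings
#                    before the encoder; pooled output -> linear head
# The encoder is multi-head self-attention with post-layer-norm residual
# blocks and a GELU feed-forward, sized for desk-scale experiments; adapter
# hooks (`import_backbone_weights`) allow substituting externally trained
# weights of matching shape for full-scale use.

#' Backbone configuration
#'
#' @param family `"autoencoder"` (pooled representation from the first,
#'   classification token) or `"autoregressive"` (from the last non-padding
#'   token, that family's convention).
#' @param hidden_size Hidden dimension d; must be divisible by `heads`.
#' @param layers Number of encoder blocks.
#' @param heads Number of attention heads.
#' @param vocab_size Token vocabulary size (see [tokenizer_spec()]).
#' @param max_length Padded sequence length.
#' @param pooling Pooling strategy; defaults to `"first_token"` for the
#'   autoencoder family and `"last_token"` for the autoregressive family;
#'   `"masked_mean"` averages non-padding positions.
#' @param dropout Named list with rates `attention`, `hidden`, `classifier`
#'   in \[0, 1).
#' @param scale_gene_ordinals If `TRUE`, the bilinear head min-max scales
#'   the raw gene ordinals to \[0, 1\] by their table sizes; off by default
#'   (the raw ordinal encoding is fed directly).
#' @return List of class `backbone_config`.
#' @export
backbone_config <- function(family = c("autoencoder", "autoregressive"),
                            hidden_size = 32L, layers = 2L, heads = 4L,
                            vocab_size = 24L, max_length = 24L,
                            pooling = NULL,
                            dropout = list(attention = 0.1, hidden = 0.1,
                                           classifier = 0.1),
                            scale_gene_ordinals = FALSE) {
  family <- match.arg(family)
  stopifnot(hidden_size %% heads == 0, layers >= 1,
            all(unlist(dropout) >= 0), all(unlist(dropout) < 1))
  if (is.null(pooling)) {
    pooling <- if (family == "autoencoder") "first_token" else "last_token"
  }
  pooling <- match.arg(pooling, c("first_token", "last_token", "masked_mean"))
  structure(list(family = family, hidden_size = as.integer(hidden_size),
                 layers = as.integer(layers), heads = as.integer(heads),
                 vocab_size = as.integer(vocab_size),
                 max_length = as.integer(max_length), pooling = pooling,
                 dropout = dropout,
                 scale_gene_ordinals = scale_gene_ordinals),
            class = "backbone_config")
}

init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

init_backbone_params <- function(config) {
  d <- config$hidden_size
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    layers[[l]] <- list(
      Wq = init_matrix(d, d), bq = numeric(d),
      Wk = init_matrix(d, d), bk = numeric(d),
      Wv = init_matrix(d, d), bv = numeric(d),
      Wo = init_matrix(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = init_matrix(d, 4 * d), b1 = numeric(4 * d),
      W2 = init_matrix(4 * d, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d)
    )
  }
  names(layers) <- paste0("l", seq_len(config$layers))
  list(
    word = init_matrix(config$vocab_size, d),
    pos = init_matrix(config$max_length, d),
    ln_g = rep(1, d), ln_b = numeric(d),
    layers = layers
  )
}

#' Build a classification model
#'
#' Assembles the backbone, the head matching the requested setting, and (for
#' the embedding setting) randomly initialized V/J gene embedding tables
#' whose padding row 0 is frozen at zero throughout training.
#'
#' @param config A [backbone_config()].
#' @param num_classes Number of epitope classes.
#' @param setting `"baseline"`, `"classification"` or `"embedding"`.
#' @param v_table_size,j_table_size Gene embedding table sizes
#'   (`vocabulary size + 2`; required for the classification and embedding
#'   settings).
#' @param gene_lr_multiplier Learning-rate multiplier for the gene tables
#'   (default 10), consumed by [parameter_groups()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `tcr_model`.
#' @export
build_model <- function(config, num_classes,
                        setting = c("baseline", "classification", "embedding"),
                        v_table_size = NULL, j_table_size = NULL,
                        gene_lr_multiplier = 10, seed = 1L) {
  setting <- match.arg(setting)
  if (setting %in% c("classification", "embedding") &&
      (is.null(v_table_size) || is.null(j_table_size))) {
    stop("setting '", setting,
         "' requires v_table_size and j_table_size", call. = FALSE)
  }
  set.seed(seed)
  d <- config$hidden_size
  params <- list(backbone = init_backbone_params(config))
  if (setting == "classification") {
    params$head <- list(A = array(rnorm(d * 2 * num_classes, sd = 0.02),
                                  dim = c(d, 2, num_classes)),
                        b = numeric(num_classes))
  } else {
    params$head <- list(A = init_matrix(num_classes, d),
                        b = numeric(num_classes))
  }
  if (setting == "embedding") {
    v_tab <- init_matrix(v_table_size, d)
    j_tab <- init_matrix(j_table_size, d)
    v_tab[1, ] <- 0  # row for gene id 0: frozen "no gene" padding
    j_tab[1, ] <- 0
    params$gene <- list(v = v_tab, j = j_tab)
  }
  structure(list(config = config, params = params, setting = setting,
                 num_classes = as.integer(num_classes),
                 v_table_size = v_table_size, j_table_size = j_table_size,
                 gene_lr_multiplier = gene_lr_multiplier),
            class = "tcr_model")
}

#' Pool final hidden states into a single vector
#'
#' @param hidden L x d matrix of final hidden states.
#' @param mask Length-L attention mask (1 at non-padding positions).
#' @param strategy `"first_token"`, `"last_token"`, or `"masked_mean"`.
#' @return Length-d vector.
#' @export
pool <- function(hidden, mask,
                 strategy = c("first_token", "last_token", "masked_mean")) {
  strategy <- match.arg(strategy)
  if (all(mask == 0)) stop("all-zero attention mask", call. = FALSE)
  switch(strategy,
         first_token = hidden[1, ],
         last_token = hidden[max(which(mask == 1)), ],
         masked_mean = colMeans(hidden[mask == 1, , drop = FALSE]))
}

#' Linear classification head
#'
#' `y = x A^T + b`: maps the pooled d-vector to one logit per class.
#'
#' @param x Pooled vector (length d).
#' @param params List with `A` (num_classes x d) and `b` (num_classes).
#' @return Logit vector.
#' @export
linear_head <- function(x, params) {
  if (ncol(params$A) != length(x)) {
    stop("linear head: A has ", ncol(params$A), " columns but x has length ",
         length(x), call. = FALSE)
  }
  as.vector(params$A %*% x + params$b)
}

#' Bilinear gene-fusion head
#'
#' `y_c = x1^T A_c x2 + b_c`, where `x1` is the pooled sequence
#' representation and `x2 = (v_ordinal, j_ordinal)` carries the gene
#' encoding; the learned `A_c` (d x 2) expresses the interaction between
#' sequence and gene usage.
#'
#' @param x1 Pooled vector (length d).
#' @param x2 Length-2 numeric vector of (V, J) gene ordinals.
#' @param params List with `A` (array d x 2 x num_classes) and `b`.
#' @return Logit vector.
#' @export
bilinear_head <- function(x1, x2, params) {
  dims <- dim(params$A)
  if (dims[1] != length(x1) || dims[2] != 2 || length(x2) != 2) {
    stop("bilinear head: shape mismatch", call. = FALSE)
  }
  C <- dims[3]
  y <- numeric(C)
  for (c in seq_len(C)) y[c] <- as.numeric(x1 %*% params$A[, , c] %*% x2)
  y + params$b
}

#' Merge gene embeddings into token embeddings
#'
#' Row i of the result is
#' `word_table[token_ids[i]] + v_table[v_ids[i] + 1] + j_table[j_ids[i] + 1]`
#' (gene id 0 addresses the frozen zero padding row, so special-token and
#' padding positions keep their plain word embeddings).
#'
#' @param token_ids Length-L token ids (1-based rows of `word_table`).
#' @param v_feature_ids,j_feature_ids Length-L gene feature ids (0 = none).
#' @param word_table Token embedding matrix.
#' @param tables List with `v` and `j` gene embedding tables.
#' @return L x d matrix.
#' @export
embed_with_genes <- function(token_ids, v_feature_ids, j_feature_ids,
                             word_table, tables) {
  if (max(v_feature_ids) + 1 > nrow(tables$v) ||
      max(j_feature_ids) + 1 > nrow(tables$j)) {
    stop("gene feature id out of table range", call. = FALSE)
  }
  word_table[token_ids, , drop = FALSE] +
    tables$v[v_feature_ids + 1, , drop = FALSE] +
    tables$j[j_feature_ids + 1, , drop = FALSE]
}

gene_ordinals_of <- function(ex) {
  c(max(ex$v_feature_ids), max(ex$j_feature_ids))
}

# Forward pass for one tokenized example. Returns logits and, when
# `keep_cache`, everything the backward pass needs.
forward_example <- function(model, ex, train = FALSE, keep_cache = train) {
  cfg <- model$config
  p <- model$params
  d <- cfg$hidden_size
  L <- cfg$max_length
  mask <- ex$attention_mask
  drop <- cfg$dropout

  E <- p$backbone$word[ex$token_ids, , drop = FALSE] +
    p$backbone$pos[seq_len(L), , drop = FALSE]
  if (model$setting == "embedding") {
    E <- E + p$gene$v[ex$v_feature_ids + 1, , drop = FALSE] +
      p$gene$j[ex$j_feature_ids + 1, , drop = FALSE]
  }
  ln0 <- layer_norm_forward(E, p$backbone$ln_g, p$backbone$ln_b)
  m0 <- dropout_mask(dim(ln0$out), drop$hidden, train)
  H <- apply_mask(ln0$out, m0)

  nh <- cfg$heads
  dk <- d / nh
  key_bias <- ifelse(mask == 0, -1e30, 0)
  layer_caches <- if (keep_cache) vector("list", cfg$layers) else NULL

  for (l in seq_len(cfg$layers)) {
    w <- p$backbone$layers[[l]]
    A_in <- H
    Q <- dense_forward(A_in, w$Wq, w$bq)
    K <- dense_forward(A_in, w$Wk, w$bk)
    V <- dense_forward(A_in, w$Wv, w$bv)
    Ctx <- matrix(0, L, d)
    Ps <- if (keep_cache) vector("list", nh) else NULL
    Pmasks <- if (keep_cache) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dk)
      S <- S + row_broadcast(key_bias, L)
      P <- row_softmax(S)
      pm <- dropout_mask(dim(P), drop$attention, train)
      Pd <- apply_mask(P, pm)
      Ctx[, idx] <- Pd %*% V[, idx, drop = FALSE]
      if (keep_cache) {
        Ps[[h]] <- P
        Pmasks[h] <- list(pm)  # list-assign so NULL (no dropout) is kept
      }
    }
    O <- dense_forward(Ctx, w$Wo, w$bo)
    mo <- dropout_mask(dim(O), drop$hidden, train)
    Od <- apply_mask(O, mo)
    ln1 <- layer_norm_forward(A_in + Od, w$ln1_g, w$ln1_b)
    H1 <- ln1$out
    F1 <- dense_forward(H1, w$W1, w$b1)
    G <- gelu(F1)
    F2 <- dense_forward(G, w$W2, w$b2)
    mf <- dropout_mask(dim(F2), drop$hidden, train)
    F2d <- apply_mask(F2, mf)
    ln2 <- layer_norm_forward(H1 + F2d, w$ln2_g, w$ln2_b)
    H <- ln2$out
    if (keep_cache) {
      layer_caches[[l]] <- list(A_in = A_in, Q = Q, K = K, V = V, Ps = Ps,
                                Pmasks = Pmasks, Ctx = Ctx, mo = mo,
                                ln1 = ln1, H1 = H1, F1 = F1, G = G, mf = mf,
                                ln2 = ln2)
    }
  }

  pooled <- pool(H, mask, cfg$pooling)
  mc <- dropout_mask(length(pooled), drop$classifier, train)
  x <- if (is.null(mc)) pooled else pooled * as.vector(mc)

  if (model$setting == "classification") {
    x2 <- gene_ordinals_of(ex)
    if (isTRUE(cfg$scale_gene_ordinals)) {
      x2 <- x2 / c(model$v_table_size, model$j_table_size)
    }
    logits <- bilinear_head(x, x2, p$head)
  } else {
    x2 <- NULL
    logits <- linear_head(x, p$head)
  }

  cache <- if (keep_cache) {
    list(ex = ex, ln0 = ln0, m0 = m0, layers = layer_caches, mask = mask,
         pooled_dropout = mc, x = x, x2 = x2, key_bias = key_bias)
  }
  list(logits = logits, cache = cache)
}

# Backward pass matching forward_example; returns a gradient tree with the
# same shape as model$params. Gene-table padding rows (row 1 <=> id 0) are
# zeroed so they stay frozen.
backward_example <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$hidden_size
  L <- cfg$max_length
  nh <- cfg$heads
  dk <- d / nh
  g <- tree_zero(model$params)

  x <- cache$x
  if (model$setting == "classification") {
    x2 <- cache$x2
    C <- model$num_classes
    dx <- numeric(d)
    for (c in seq_len(C)) {
      g$head$A[, , c] <- dlogits[c] * outer(x, x2)
      dx <- dx + dlogits[c] * as.vector(p$head$A[, , c] %*% x2)
    }
    g$head$b <- dlogits
  } else {
    g$head$A <- outer(dlogits, x)
    g$head$b <- dlogits
    dx <- as.vector(t(p$head$A) %*% dlogits)
  }
  if (!is.null(cache$pooled_dropout)) dx <- dx * as.vector(cache$pooled_dropout)

  dH <- matrix(0, L, d)
  mask <- cache$mask
  switch(cfg$pooling,
         first_token = { dH[1, ] <- dx },
         last_token = { dH[max(which(mask == 1)), ] <- dx },
         masked_mean = {
           rows <- which(mask == 1)
           dH[rows, ] <- matrix(dx / length(rows), length(rows), d,
                                byrow = TRUE)
         })

  for (l in rev(seq_len(cfg$layers))) {
    w <- p$backbone$layers[[l]]
    cc <- cache$layers[[l]]
    lb2 <- layer_norm_backward(dH, cc$ln2, w$ln2_g)
    g$backbone$layers[[l]]$ln2_g <- lb2$dg
    g$backbone$layers[[l]]$ln2_b <- lb2$db
    dH1 <- lb2$dX
    dF2 <- apply_mask(lb2$dX, cc$mf)
    g$backbone$layers[[l]]$W2 <- t(cc$G) %*% dF2
    g$backbone$layers[[l]]$b2 <- colSums(dF2)
    dG <- dF2 %*% t(w$W2)
    dF1 <- dG * gelu_grad(cc$F1)
    g$backbone$layers[[l]]$W1 <- t(cc$H1) %*% dF1
    g$backbone$layers[[l]]$b1 <- colSums(dF1)
    dH1 <- dH1 + dF1 %*% t(w$W1)
    lb1 <- layer_norm_backward(dH1, cc$ln1, w$ln1_g)
    g$backbone$layers[[l]]$ln1_g <- lb1$dg
    g$backbone$layers[[l]]$ln1_b <- lb1$db
    dA_in <- lb1$dX
    dO <- apply_mask(lb1$dX, cc$mo)
    g$backbone$layers[[l]]$Wo <- t(cc$Ctx) %*% dO
    g$backbone$layers[[l]]$bo <- colSums(dO)
    dCtx <- dO %*% t(w$Wo)
    dQ <- matrix(0, L, d)
    dK <- matrix(0, L, d)
    dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      P <- cc$Ps[[h]]
      pm <- cc$Pmasks[[h]]
      Pd <- apply_mask(P, pm)
      dCtxh <- dCtx[, idx, drop = FALSE]
      dPd <- dCtxh %*% t(cc$V[, idx, drop = FALSE])
      dV[, idx] <- t(Pd) %*% dCtxh
      dP <- apply_mask(dPd, pm)
      dS <- row_softmax_backward(dP, P)
      dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE] / sqrt(dk)
      dK[, idx] <- t(dS) %*% cc$Q[, idx, drop = FALSE] / sqrt(dk)
    }
    g$backbone$layers[[l]]$Wq <- t(cc$A_in) %*% dQ
    g$backbone$layers[[l]]$bq <- colSums(dQ)
    g$backbone$layers[[l]]$Wk <- t(cc$A_in) %*% dK
    g$backbone$layers[[l]]$bk <- colSums(dK)
    g$backbone$layers[[l]]$Wv <- t(cc$A_in) %*% dV
    g$backbone$layers[[l]]$bv <- colSums(dV)
    dA_in <- dA_in + dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
    dH <- dA_in
  }

  dH <- apply_mask(dH, cache$m0)
  lb0 <- layer_norm_backward(dH, cache$ln0, p$backbone$ln_g)
  g$backbone$ln_g <- lb0$dg
  g$backbone$ln_b <- lb0$db
  dE <- lb0$dX

  ex <- cache$ex
  acc <- rowsum(dE, group = ex$token_ids)
  g$backbone$word[as.integer(rownames(acc)), ] <-
    g$backbone$word[as.integer(rownames(acc)), , drop = FALSE] + acc
  g$backbone$pos[seq_len(L), ] <- g$backbone$pos[seq_len(L), ] + dE
  if (model$setting == "embedding") {
    accv <- rowsum(dE, group = ex$v_feature_ids + 1)
    g$gene$v[as.integer(rownames(accv)), ] <-
      g$gene$v[as.integer(rownames(accv)), , drop = FALSE] + accv
    accj <- rowsum(dE, group = ex$j_feature_ids + 1)
    g$gene$j[as.integer(rownames(accj)), ] <-
      g$gene$j[as.integer(rownames(accj)), , drop = FALSE] + accj
    g$gene$v[1, ] <- 0  # padding rows stay frozen
    g$gene$j[1, ] <- 0
  }
  g
}

#' Forward pass over a batch of tokenized examples
#'
#' @param model A [build_model()] result.
#' @param examples List of `tokenized_example`s (with gene features attached
#'   when the setting consumes them).
#' @param train Apply dropout (training mode)?
#' @return Matrix of logits, one row per example.
#' @export
model_forward <- function(model, examples, train = FALSE) {
  logits <- matrix(0, length(examples), model$num_classes)
  for (i in seq_along(examples)) {
    logits[i, ] <- forward_example(model, examples[[i]], train = train,
                                   keep_cache = FALSE)$logits
  }
  logits
}

#' Class probabilities and hard predictions
#'
#' @inheritParams model_forward
#' @return List with `probs` (rows summing to 1) and `pred` (integer class
#'   ids).
#' @export
predict_classes <- function(model, examples) {
  logits <- model_forward(model, examples)
  probs <- t(apply(logits, 1, softmax_vec))
  list(probs = probs, pred = max.col(probs, ties.method = "first"))
}

#' Optimizer parameter groups
#'
#' The embedding setting trains its randomly initialized gene tables at an
#' increased rate (default 10 x the base learning rate) so they catch up
#' with the already-informative backbone; all other trainables use the base
#' rate. The frozen gene-padding rows receive no updates (their gradients
#' are identically zero).
#'
#' @param model A [build_model()] result.
#' @param base_lr Base learning rate.
#' @param multiplier Gene-table multiplier (default the model's
#'   `gene_lr_multiplier`).
#' @return List of groups, each `list(name, lr, paths)` where `paths` are
#'   parameter-tree addresses.
#' @export
parameter_groups <- function(model, base_lr,
                             multiplier = model$gene_lr_multiplier) {
  all_paths <- names(tree_leaves(model$params))
  gene_paths <- grep("^gene\\.", all_paths, value = TRUE)
  if (model$setting != "embedding" || length(gene_paths) == 0) {
    return(list(list(name = "main", lr = base_lr, multiplier = 1,
                     paths = all_paths)))
  }
  list(
    list(name = "main", lr = base_lr, multiplier = 1,
         paths = setdiff(all_paths, gene_paths)),
    list(name = "gene_embeddings", lr = base_lr * multiplier,
         multiplier = multiplier, paths = gene_paths)
  )
}

#' Import externally trained backbone weights
#'
#' Adapter hook for full-scale use: replaces backbone leaves whose names and
#' shapes match the supplied tree.
#'
#' @param model A [build_model()] result.
#' @param weights Nested list shaped like `model$params$backbone` (possibly
#'   partial).
#' @return The model with matching weights replaced.
#' @export
import_backbone_weights <- function(model, weights) {
  incoming <- tree_leaves(weights)
  for (path in names(incoming)) {
    current <- tree_get(model$params$backbone, path)
    value <- incoming[[path]]
    if (is.null(current) || !identical(dim_or_len(current), dim_or_len(value))) {
      stop("backbone weight '", path, "' missing or shape-mismatched",
           call. = FALSE)
    }
    model$params$backbone <- tree_set(model$params$backbone, path, value)
  }
  model
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)
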