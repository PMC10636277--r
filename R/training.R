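# Fine-tuning loop: Adam with decoupled weight decay, linear warmup then
# linear decay, gradient accumulation, per-group learning rates (gene
# embedding tables train faster), early stopping on validation loss, and a
# pluggable hyperparameter-search driver.

#' Training configuration
#'
#' Houses the tunable hyperparameters of the fine-tuning loop. Dropout
#' rates, when supplied, override the model's backbone configuration at the
#' start of training so the whole 10-dimensional search space lives in one
#' object.
#'
#' @param max_epochs Maximum training epochs (default 50).
#' @param early_stopping_patience Evaluation rounds without validation-loss
#'   improvement before stopping (default 5; evaluation happens once per
#'   epoch).
#' @param train_batch,eval_batch Micro-batch sizes (defaults 1 and 8).
#' @param base_lr Base learning rate.
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (biases and layer-norm parameters are exempt).
#' @param warmup_ratio Fraction of total update steps spent linearly warming
#'   the learning rate from 0; afterwards it decays linearly to 0.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param dropout Optional named list (`attention`, `hidden`, `classifier`)
#'   overriding the model's dropout rates.
#' @param gradient_accumulation Micro-batches accumulated per parameter
#'   update.
#' @param gamma Focal-loss focusing parameter.
#' @param seed Integer seed governing shuffling, dropout and initialization
#'   of the run.
#' @return List of class `train_config`.
#' @export
train_config <- function(max_epochs = 50L, early_stopping_patience = 5L,
                         train_batch = 1L, eval_batch = 8L,
                         base_lr = 5e-4, weight_decay = 0.01,
                         warmup_ratio = 0.1, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, dropout = NULL,
                         gradient_accumulation = 1L, gamma = 2,
                         seed = 1L) {
  stopifnot(train_batch >= 1, eval_batch >= 1, gradient_accumulation >= 1,
            warmup_ratio >= 0, warmup_ratio < 1, gamma >= 0,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0, adam_beta2 < 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 train_batch = as.integer(train_batch),
                 eval_batch = as.integer(eval_batch),
                 base_lr = base_lr, weight_decay = weight_decay,
                 warmup_ratio = warmup_ratio, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, dropout = dropout,
                 gradient_accumulation = as.integer(gradient_accumulation),
                 gamma = gamma, seed = as.integer(seed)),
            class = "train_config")
}

schedule_lr <- function(step, total_steps, warmup_steps) {
  if (warmup_steps > 0 && step <= warmup_steps) return(step / warmup_steps)
  if (total_steps <= warmup_steps) return(1)
  max(0, (total_steps - step) / (total_steps - warmup_steps))
}

leaf_decays <- function(path) {
  leaf <- utils::tail(strsplit(path, ".", fixed = TRUE)[[1]], 1)
  !(startsWith(leaf, "b") || startsWith(leaf, "ln"))
}

# One Adam update over the whole parameter tree; returns updated trees.
adam_step <- function(p, g, m, v, t, lr_leaf, wd_leaf, beta1, beta2,
                      eps = 1e-8, path = "") {
  if (is.list(p)) {
    for (nm in names(p)) {
      sub <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], t, lr_leaf,
                       wd_leaf, beta1, beta2, eps,
                       if (nzchar(path)) paste(path, nm, sep = ".") else nm)
      p[[nm]] <- sub$p
      m[[nm]] <- sub$m
      v[[nm]] <- sub$v
    }
    return(list(p = p, m = m, v = v))
  }
  lr <- lr_leaf(path)
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  p <- p - lr * (mh / (sqrt(vh) + eps) + wd_leaf(path) * p)
  list(p = p, m = m, v = v)
}

eval_loss_and_f1 <- function(model, examples, labels, gamma) {
  logits <- model_forward(model, examples, train = FALSE)
  probs <- t(apply(logits, 1, softmax_vec))
  loss <- focal_loss(probs, labels,
                     loss_config(gamma = gamma, reduction = "mean"))
  pred <- max.col(probs, ties.method = "first")
  f1 <- classification_metrics(labels, pred)$weighted_f1
  list(loss = as.numeric(loss), f1 = f1)
}

#' Fine-tune a model
#'
#' Runs the training loop on the train partition, evaluating once per epoch
#' on the validation partition, and returns the checkpoint with the best
#' validation loss. Fixed seed and single-device execution give
#' bitwise-reproducible histories.
#'
#' @param model A [build_model()] result.
#' @param data List with `train` and `validation`, each a list holding
#'   `examples` (tokenized, gene features attached) and `labels` (integer
#'   class ids).
#' @param config A [train_config()].
#' @return List with `model` (best-validation checkpoint) and `history`
#'   (data.frame of per-epoch `train_loss`, `val_loss`, `val_weighted_f1`,
#'   with attributes `stopping_epoch`, `best_epoch`, `update_count`).
#' @export
train <- function(model, data, config = train_config()) {
  if (length(data$train$examples) == 0 || length(data$validation$examples) == 0) {
    stop("train and validation partitions must be non-empty", call. = FALSE)
  }
  if (!is.null(config$dropout)) {
    model$config$dropout <- utils::modifyList(model$config$dropout,
                                              config$dropout)
  }
  set.seed(config$seed)
  n_train <- length(data$train$examples)
  micro_per_epoch <- ceiling(n_train / config$train_batch)
  updates_per_epoch <- ceiling(micro_per_epoch / config$gradient_accumulation)
  total_updates <- config$max_epochs * updates_per_epoch
  warmup_steps <- floor(config$warmup_ratio * total_updates)

  groups <- parameter_groups(model, config$base_lr)
  lr_mult <- setNames(rep(1, 0), character(0))
  for (gr in groups) lr_mult[gr$paths] <- gr$multiplier
  sched <- 1
  lr_leaf <- function(path) config$base_lr * sched * lr_mult[[path]]
  wd_leaf <- function(path) if (leaf_decays(path)) config$weight_decay else 0

  m_state <- tree_zero(model$params)
  v_state <- tree_zero(model$params)
  lcfg <- loss_config(gamma = config$gamma, reduction = "sum")

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_weighted_f1 = numeric(0))
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  stall <- 0L
  update_count <- 0L
  stopping_epoch <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    order <- sample.int(n_train)
    grad_acc <- NULL
    acc_n <- 0L
    epoch_loss <- 0
    micro_starts <- seq(1, n_train, by = config$train_batch)
    for (b in seq_along(micro_starts)) {
      idx <- order[micro_starts[b]:min(micro_starts[b] + config$train_batch - 1,
                                       n_train)]
      for (i in idx) {
        fw <- forward_example(model, data$train$examples[[i]], train = TRUE)
        probs <- softmax_vec(fw$logits)
        target <- data$train$labels[i]
        epoch_loss <- epoch_loss +
          as.numeric(focal_loss(probs, target, lcfg))
        dlogits <- focal_grad_logits(fw$logits, target, config$gamma)
        g <- backward_example(model, fw$cache, dlogits)
        grad_acc <- if (is.null(grad_acc)) g else tree_map2(grad_acc, g, `+`)
      }
      acc_n <- acc_n + 1L
      if (acc_n == config$gradient_accumulation || b == length(micro_starts)) {
        update_count <- update_count + 1L
        sched <- schedule_lr(update_count, total_updates, warmup_steps)
        upd <- adam_step(model$params, grad_acc, m_state, v_state,
                         update_count, lr_leaf, wd_leaf,
                         config$adam_beta1, config$adam_beta2)
        model$params <- upd$p
        m_state <- upd$m
        v_state <- upd$v
        grad_acc <- NULL
        acc_n <- 0L
      }
    }
    ev <- eval_loss_and_f1(model, data$validation$examples,
                           data$validation$labels, config$gamma)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_train,
      val_loss = ev$loss, val_weighted_f1 = ev$f1))
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, params = model$params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) {
        stopping_epoch <- epoch
        break
      }
    }
    stopping_epoch <- epoch
  }

  model$params <- best$params
  attr(history, "stopping_epoch") <- stopping_epoch
  attr(history, "best_epoch") <- best$epoch
  attr(history, "update_count") <- update_count
  list(model = model, history = history)
}

#' Declare a hyperparameter search space
#'
#' @param ... Entries of the form
#'   `list(name = , kind = c("uniform", "loguniform", "categorical"),
#'   range = )` where `range` is a length-2 numeric bound (non-degenerate)
#'   or, for categoricals, the value set.
#' @return List of class `search_space`.
#' @export
search_space <- function(...) {
  entries <- list(...)
  for (e in entries) {
    stopifnot(is.character(e$name),
              e$kind %in% c("uniform", "loguniform", "categorical"))
    if (e$kind != "categorical") {
      stopifnot(length(e$range) == 2, e$range[1] < e$range[2])
    } else {
      stopifnot(length(e$range) >= 2)
    }
  }
  structure(entries, class = "search_space")
}

#' Default 10-hyperparameter search space
#'
#' Covers gradient accumulation, learning rate, weight decay, the three
#' dropout rates, the Adam betas, the warmup ratio and the focal-loss gamma.
#' Ranges are shipped configuration defaults for desk-scale runs, meant to
#' be overridden per experiment.
#'
#' @return A [search_space()].
#' @export
default_search_space <- function() {
  search_space(
    list(name = "base_lr", kind = "loguniform", range = c(1e-5, 1e-2)),
    list(name = "weight_decay", kind = "uniform", range = c(0, 0.3)),
    list(name = "warmup_ratio", kind = "uniform", range = c(0, 0.2)),
    list(name = "adam_beta1", kind = "uniform", range = c(0.8, 0.95)),
    list(name = "adam_beta2", kind = "uniform", range = c(0.9, 0.9999)),
    list(name = "attention_dropout", kind = "uniform", range = c(0, 0.5)),
    list(name = "hidden_dropout", kind = "uniform", range = c(0, 0.5)),
    list(name = "classifier_dropout", kind = "uniform", range = c(0, 0.5)),
    list(name = "gradient_accumulation", kind = "categorical",
         range = c(1L, 2L, 4L, 8L)),
    list(name = "gamma", kind = "uniform", range = c(0, 5))
  )
}

sample_trial_config <- function(space) {
  cfg <- list()
  for (e in space) {
    cfg[[e$name]] <- switch(e$kind,
      uniform = runif(1, e$range[1], e$range[2]),
      loguniform = exp(runif(1, log(e$range[1]), log(e$range[2]))),
      categorical = e$range[[sample.int(length(e$range), 1)]]
    )
  }
  cfg
}

#' Hyperparameter search
#'
#' Maximizes `objective` (e.g. validation weighted F1) over the space. The
#' built-in `"random"` strategy is a seeded self-contained sampler; the
#' `"tpe-adapter"` strategy delegates proposal and feedback to an external
#' Bayesian optimizer supplied as `sampler` (a list with functions
#' `ask(trial_index)` returning a config and `tell(config, score)`), since
#' the optimizer itself is not this package's contribution.
#'
#' @param space A [search_space()].
#' @param n_trials Number of trials (>= 1).
#' @param objective Function config -> numeric score (higher is better).
#' @param strategy `"random"` or `"tpe-adapter"`.
#' @param seed Integer seed (random strategy).
#' @param sampler External optimizer adapter (tpe-adapter strategy).
#' @return List of class `search_result` with `best_config`, `best_score`,
#'   and `trials` (list of `list(config, score)`).
#' @export
hyperparameter_search <- function(space, n_trials, objective,
                                  strategy = c("random", "tpe-adapter"),
                                  seed = 1L, sampler = NULL) {
  strategy <- match.arg(strategy)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (strategy == "tpe-adapter" && is.null(sampler)) {
    stop("strategy 'tpe-adapter' requires an external optimizer via ",
         "`sampler` (list with ask/tell functions)", call. = FALSE)
  }
  if (strategy == "random") set.seed(seed)
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    cfg <- if (strategy == "random") sample_trial_config(space) else
      sampler$ask(t)
    score <- objective(cfg)
    if (strategy == "tpe-adapter") sampler$tell(cfg, score)
    trials[[t]] <- list(config = cfg, score = score)
  }
  scores <- vapply(trials, function(x) x$score, numeric(1))
  best <- which.max(scores)
  structure(list(best_config = trials[[best]]$config,
                 best_score = scores[best], trials = trials),
            class = "search_result")
}
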