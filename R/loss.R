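# Multi-class cross-entropy and focal loss. Focal loss rescales the
# cross-entropy of each sample by (1 - p_true)^gamma, shrinking the
# contribution of well-classified (typically large-class) samples so the
# hard, small classes drive the gradient. Natural logarithms throughout.

#' Loss configuration
#'
#' @param gamma Focusing parameter, >= 0. 0 recovers plain cross-entropy;
#'   2 is the customary default for single runs, and the training module
#'   treats gamma as a tunable hyperparameter.
#' @param eps Probabilities are clamped below at `eps` before taking logs so
#'   a zero probability at the true class yields a large finite loss; clamp
#'   events are flagged, not silently absorbed.
#' @param reduction `"mean"` or `"sum"` over a batch.
#' @return List of class `loss_config`.
#' @export
loss_config <- function(gamma = 2, eps = 1e-12,
                        reduction = c("mean", "sum")) {
  stopifnot(gamma >= 0, eps > 0)
  structure(list(gamma = gamma, eps = eps,
                 reduction = match.arg(reduction)),
            class = "loss_config")
}

# Normalizes (probs, target) into a matrix of probabilities and an integer
# vector of true-class columns; accepts a single probability vector or a
# batch matrix (rows = samples), and targets as indices or one-hot.
as_loss_batch <- function(probs, target) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  if (is.matrix(target)) {
    stopifnot(all(rowSums(target) == 1))
    target <- max.col(target, ties.method = "first")
  }
  stopifnot(nrow(probs) == length(target),
            all(target >= 1), all(target <= ncol(probs)))
  list(probs = probs, target = as.integer(target))
}

#' Multi-class cross-entropy
#'
#' For one-hot targets this is `-ln p_true` per sample.
#'
#' @param probs Per-class probability vector, or a batch matrix with one row
#'   per sample (rows summing to 1).
#' @param target True class index (1-based), vector for a batch, or a
#'   one-hot matrix.
#' @param config A [loss_config()]; `gamma` is ignored here.
#' @return Non-negative scalar (reduced over the batch). Attribute
#'   `clamped` reports how many true-class probabilities hit the clamp.
#' @export
cross_entropy <- function(probs, target, config = loss_config()) {
  focal_loss(probs, target, config = loss_config(gamma = 0, eps = config$eps,
                                                 reduction = config$reduction))
}

#' Multi-class focal loss
#'
#' `FL = -(1 - p_true)^gamma * ln(p_true)` per sample (one-hot targets);
#' equals cross-entropy exactly when `gamma = 0` or `p_true = 1`.
#'
#' @inheritParams cross_entropy
#' @return Non-negative scalar (reduced over the batch), with attribute
#'   `clamped` counting clamp events at the true class.
#' @export
focal_loss <- function(probs, target, config = loss_config()) {
  b <- as_loss_batch(probs, target)
  p_true <- b$probs[cbind(seq_along(b$target), b$target)]
  clamped <- sum(p_true < config$eps)
  p_true <- pmax(p_true, config$eps)
  per_sample <- -(1 - p_true)^config$gamma * log(p_true)
  out <- switch(config$reduction, mean = mean(per_sample),
                sum = sum(per_sample))
  attr(out, "clamped") <- clamped
  out
}

# Gradient of the (summed) focal loss with respect to logits, for one
# sample. Derivation: with p = softmax(z) and t the true class,
# FL depends on z only through p_t; dFL/dp_t =
# gamma*(1-p_t)^(gamma-1)*log(p_t) - (1-p_t)^gamma / p_t, and
# dp_t/dz_j = p_t (1[j==t] - p_j). gamma = 0 recovers (p - onehot).
focal_grad_logits <- function(logits, target, gamma, eps = 1e-12) {
  p <- softmax_vec(logits)
  t <- target
  p_t <- max(p[t], eps)
  if (gamma == 0) {
    g <- p
    g[t] <- g[t] - 1
    return(g)
  }
  coef <- gamma * (1 - p_t)^(gamma - 1) * log(p_t) - (1 - p_t)^gamma / p_t
  g <- -coef * p_t * p
  g[t] <- g[t] + coef * p_t
  g
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
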