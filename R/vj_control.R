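# Control model: a plain feed-forward network on one-hot V/J gene inputs
# (no sequence information), used to measure how much of a classifier's
# performance is attributable to gene usage alone.

#' Fit the V/J-only feed-forward control model
#'
#' A feed-forward network taking the one-hot encoded V and J gene ordinals
#' (concatenated) through two hidden layers with rectified-linear
#' activations to a softmax output, trained with categorical cross-entropy
#' and full-batch Adam.
#'
#' @param v_ordinals,j_ordinals Integer gene ordinals (>= 1) per sample.
#' @param labels Integer class ids (1-based) per sample.
#' @param v_size,j_size One-hot input widths (use the vocabulary
#'   `table_size`).
#' @param num_classes Number of classes.
#' @param hidden Sizes of the two hidden layers.
#' @param epochs Training epochs (full-batch updates).
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return Object of class `vj_control_model`.
#' @export
fit_vj_control <- function(v_ordinals, j_ordinals, labels, v_size, j_size,
                           num_classes, hidden = c(32L, 32L), epochs = 200L,
                           lr = 0.01, seed = 1L) {
  stopifnot(length(v_ordinals) == length(labels),
            length(j_ordinals) == length(labels),
            all(v_ordinals >= 1), all(j_ordinals >= 1))
  set.seed(seed)
  n <- length(labels)
  X <- matrix(0, n, v_size + j_size)
  X[cbind(seq_len(n), v_ordinals)] <- 1
  X[cbind(seq_len(n), v_size + j_ordinals)] <- 1
  Y <- matrix(0, n, num_classes)
  Y[cbind(seq_len(n), labels)] <- 1

  params <- list(
    W1 = init_matrix(ncol(X), hidden[1]), b1 = numeric(hidden[1]),
    W2 = init_matrix(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
    W3 = init_matrix(hidden[2], num_classes), b3 = numeric(num_classes)
  )
  m <- tree_zero(params)
  v <- tree_zero(params)
  losses <- numeric(epochs)
  for (t in seq_len(epochs)) {
    H1 <- pmax(dense_forward(X, params$W1, params$b1), 0)
    H2 <- pmax(dense_forward(H1, params$W2, params$b2), 0)
    Z <- dense_forward(H2, params$W3, params$b3)
    P <- row_softmax(Z)
    losses[t] <- -mean(log(pmax(P[Y == 1], 1e-12)))
    dZ <- (P - Y) / n
    g <- list(
      W3 = t(H2) %*% dZ, b3 = colSums(dZ),
      W2 = NULL, b2 = NULL, W1 = NULL, b1 = NULL
    )
    dH2 <- (dZ %*% t(params$W3)) * (H2 > 0)
    g$W2 <- t(H1) %*% dH2
    g$b2 <- colSums(dH2)
    dH1 <- (dH2 %*% t(params$W2)) * (H1 > 0)
    g$W1 <- t(X) %*% dH1
    g$b1 <- colSums(dH1)
    g <- g[names(params)]
    m <- tree_map2(m, g, function(a, b) 0.9 * a + 0.1 * b)
    v <- tree_map2(v, g, function(a, b) 0.999 * a + 0.001 * b^2)
    mh <- tree_map(m, function(a) a / (1 - 0.9^t))
    vh <- tree_map(v, function(a) a / (1 - 0.999^t))
    upd <- tree_map2(mh, vh, function(a, b) lr * a / (sqrt(b) + 1e-8))
    params <- tree_map2(params, upd, `-`)
  }
  structure(list(params = params, v_size = v_size, j_size = j_size,
                 num_classes = num_classes, losses = losses),
            class = "vj_control_model")
}

#' Predict class probabilities from gene usage alone
#'
#' @param object A [fit_vj_control()] model.
#' @param v_ordinals,j_ordinals Integer gene ordinals per sample.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
predict.vj_control_model <- function(object, v_ordinals, j_ordinals, ...) {
  n <- length(v_ordinals)
  X <- matrix(0, n, object$v_size + object$j_size)
  X[cbind(seq_len(n), v_ordinals)] <- 1
  X[cbind(seq_len(n), object$v_size + j_ordinals)] <- 1
  p <- object$params
  H1 <- pmax(dense_forward(X, p$W1, p$b1), 0)
  H2 <- pmax(dense_forward(H1, p$W2, p$b2), 0)
  row_softmax(dense_forward(H2, p$W3, p$b3))
}
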