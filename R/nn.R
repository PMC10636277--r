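# Internal neural-network primitives: nested parameter trees of numeric
# arrays, and forward/backward pairs for the layers the encoder is built
# from. Backward passes are hand-derived; test-model.R checks them against
# central finite differences.

# --- parameter-tree utilities -----------------------------------------------

tree_map <- function(tree, f) {
  if (is.list(tree)) lapply(tree, tree_map, f = f) else f(tree)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(tree) tree_map(tree, function(x) x * 0)

tree_leaves <- function(tree, prefix = "") {
  if (is.list(tree)) {
    out <- list()
    for (nm in names(tree)) {
      out <- c(out, tree_leaves(tree[[nm]],
                                if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm))
    }
    out
  } else {
    setNames(list(tree), prefix)
  }
}

tree_get <- function(tree, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) tree <- tree[[p]]
  tree
}

tree_set <- function(tree, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    tree[[parts]] <- value
    return(tree)
  }
  tree[[parts[1]]] <- tree_set(tree[[parts[1]]], paste(parts[-1], collapse = "."), value)
  tree
}

# --- layers ------------------------------------------------------------------

row_broadcast <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

# y = x W + b, rows of x are positions
dense_forward <- function(X, W, b) X %*% W + row_broadcast(b, nrow(X))

layer_norm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv_std <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv_std
  out <- xhat * row_broadcast(g, nrow(X)) + row_broadcast(b, nrow(X))
  list(out = out, xhat = xhat, inv_std = inv_std)
}

layer_norm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * row_broadcast(g, nrow(dY))
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- cache$inv_std *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

row_softmax <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

row_softmax_backward <- function(dP, P) P * (dP - rowSums(dP * P))

dropout_mask <- function(dim, rate, train) {
  if (!train || rate <= 0) return(NULL)
  array((runif(prod(dim)) >= rate) / (1 - rate), dim = dim)
}

apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask
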