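test_that("pooling strategies return the advertised rows", {
  H <- matrix(1:12, nrow = 3, ncol = 4, byrow = TRUE)
  mask <- c(1, 1, 0)
  expect_equal(pool(H, mask, "first_token"), H[1, ])
  expect_equal(pool(H, mask, "last_token"), H[2, ])
  expect_equal(pool(H, mask, "masked_mean"), colMeans(H[1:2, ]))

  # constant rows pool to that constant for every strategy
  Hc <- matrix(rep(c(1, 3, 2, 5), each = 3), nrow = 3)
  for (s in c("first_token", "last_token", "masked_mean")) {
    expect_equal(pool(Hc, c(1, 1, 1), s), c(1, 3, 2, 5))
  }

  # hand mean: values 1 and 3 with mask (1,1,0) -> 2
  Hm <- matrix(c(1, 3, 99), ncol = 1)
  expect_equal(pool(Hm, c(1, 1, 0), "masked_mean"), 2)

  expect_error(pool(H, c(0, 0, 0), "first_token"), "mask")
})

test_that("linear head matches hand-expanded algebra", {
  # identity A, zero b -> y = x
  x <- c(0.3, -1, 2)
  expect_equal(linear_head(x, list(A = diag(3), b = rep(0, 3))), x)
  # zero A -> y = b
  expect_equal(linear_head(x, list(A = matrix(0, 2, 3), b = c(1, -2))),
               c(1, -2))
  # hand expansion
  y <- linear_head(c(1, 2), list(A = rbind(c(1, 1), c(2, 0)),
                                 b = c(0.5, -1)))
  expect_equal(y, c(3.5, 1))
  expect_error(linear_head(c(1, 2, 3), list(A = matrix(0, 2, 2), b = c(0, 0))),
               "columns")
})

test_that("bilinear head matches hand-expanded algebra", {
  d <- 2
  A0 <- array(0, dim = c(d, 2, 3))
  expect_equal(bilinear_head(c(1, 1), c(3, 4), list(A = A0, b = c(0.5, 1, -1))),
               c(0.5, 1, -1))
  # zero gene encoding -> bias regardless of x1
  A <- array(rnorm(d * 2 * 3), dim = c(d, 2, 3))
  expect_equal(bilinear_head(rnorm(2), c(0, 0), list(A = A, b = c(1, 2, 3))),
               c(1, 2, 3))
  # identity slice: x1=(1,2), x2=(3,4) -> 1*3 + 2*4 = 11
  A1 <- array(diag(2), dim = c(2, 2, 1))
  expect_equal(bilinear_head(c(1, 2), c(3, 4), list(A = A1, b = 0)), 11)
  expect_error(bilinear_head(c(1, 2, 3), c(1, 2), list(A = A1, b = 0)),
               "mismatch")
})

test_that("gene embeddings merge additively and leave gene-id-0 positions untouched", {
  word <- matrix(1:8, 4, 2)
  vt <- rbind(c(0, 0), c(10, 20), c(30, 40))
  jt <- rbind(c(0, 0), c(1, 2))
  ids <- c(1, 3, 4, 2)
  # all gene ids 0 -> plain word embeddings
  out0 <- embed_with_genes(ids, rep(0, 4), rep(0, 4), word,
                           list(v = vt, j = jt))
  expect_equal(out0, word[ids, ])
  # hand-added rows
  out <- embed_with_genes(ids, c(0, 2, 2, 0), c(0, 1, 1, 0), word,
                          list(v = vt, j = jt))
  expect_equal(out[1, ], word[1, ])
  expect_equal(out[2, ], word[3, ] + vt[3, ] + jt[2, ])
  expect_equal(out[4, ], word[2, ])
  expect_error(embed_with_genes(ids, c(0, 9, 0, 0), rep(0, 4), word,
                                list(v = vt, j = jt)), "range")
})

test_that("embedding-setting forward with zero gene ids equals baseline with shared weights", {
  base <- tiny_model("baseline", seed = 11)
  emb <- tiny_model("embedding", seed = 11)
  # identical backbone + head draws by construction of the init order
  expect_identical(base$params$backbone, emb$params$backbone)
  spec <- tiny_spec()
  ex <- tokenize("CASSLG", spec, label_id = 1)  # gene ids all zero
  lb <- tcrtyper:::forward_example(base, ex)$logits
  le <- tcrtyper:::forward_example(emb, ex)$logits
  expect_equal(lb, le, tolerance = 1e-12)
})

test_that("forward passes are pure functions and softmax rows sum to 1", {
  for (setting in c("baseline", "classification", "embedding")) {
    m <- tiny_model(setting)
    exs <- list(example_of("CASSL"), example_of("CARNT", v = 2, j = 1))
    l1 <- model_forward(m, exs)
    l2 <- model_forward(m, exs)
    expect_identical(l1, l2)
    expect_equal(dim(l1), c(2L, 3L))
    pr <- predict_classes(m, exs)
    expect_equal(rowSums(pr$probs), c(1, 1), tolerance = 1e-12)
  }
})

test_that("backward pass matches central finite differences on every leaf group", {
  set.seed(4)
  for (setting in c("baseline", "classification", "embedding")) {
    m <- tiny_model(setting, seed = 42)
    ex <- example_of("CASS", v = 3, j = 2, label = 2)
    fw <- tcrtyper:::forward_example(m, ex, train = FALSE, keep_cache = TRUE)
    dlog <- tcrtyper:::focal_grad_logits(fw$logits, 2, 2)
    g <- tcrtyper:::backward_example(m, fw$cache, dlog)
    leaves <- tcrtyper:::tree_leaves(m$params)
    for (path in names(leaves)) {
      n <- length(leaves[[path]])
      idx <- sample.int(n, min(3, n))
      if (path %in% c("gene.v", "gene.j")) {
        # skip the frozen padding row (column-major index 1 + k*nrow)
        nr <- nrow(leaves[[path]])
        idx <- idx[(idx - 1) %% nr + 1 != 1]
        if (length(idx) == 0) next
      }
      num <- numeric_grad_leaf(m, ex, 2, 2, path, idx)
      ana <- tcrtyper:::tree_get(g, path)[idx]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = paste("grad", setting, path))
    }
  }
})

test_that("gene-table padding rows receive zero gradient and never move", {
  m <- tiny_model("embedding")
  ex <- example_of("CASSL", v = 3, j = 2, label = 1)
  fw <- tcrtyper:::forward_example(m, ex, train = FALSE, keep_cache = TRUE)
  g <- tcrtyper:::backward_example(m, fw$cache,
                                   tcrtyper:::focal_grad_logits(fw$logits, 1, 2))
  expect_equal(g$gene$v[1, ], rep(0, 8))
  expect_equal(g$gene$j[1, ], rep(0, 8))
  expect_equal(m$params$gene$v[1, ], rep(0, 8))

  # after a few training steps the rows are still exactly zero
  data <- list(
    train = list(examples = replicate(6, example_of(random_cdr3(6)),
                                      simplify = FALSE),
                 labels = rep(1:3, 2)),
    validation = list(examples = list(example_of("CASS")), labels = 2L)
  )
  fit <- train(m, data, train_config(max_epochs = 2, base_lr = 1e-3, seed = 1))
  expect_equal(fit$model$params$gene$v[1, ], rep(0, 8))
  expect_equal(fit$model$params$gene$j[1, ], rep(0, 8))
})

test_that("parameter groups put gene tables at the multiplied rate", {
  emb <- tiny_model("embedding")
  groups <- parameter_groups(emb, base_lr = 1e-5)
  gene <- Filter(function(g) g$name == "gene_embeddings", groups)[[1]]
  expect_equal(gene$lr, 1e-4)
  expect_setequal(gene$paths, c("gene.v", "gene.j"))

  base <- tiny_model("baseline")
  expect_length(parameter_groups(base, 1e-5), 1)

  emb$gene_lr_multiplier <- 1
  groups1 <- parameter_groups(emb, 1e-5)
  expect_true(all(vapply(groups1, function(g) g$lr, numeric(1)) == 1e-5))
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- tiny_model("embedding")
  dir <- tempfile()
  save_model(m, dir, class_levels = c("a", "b", "c"))
  back <- load_model(dir)
  expect_equal(back$class_levels, c("a", "b", "c"))
  ex <- example_of("CASSL", v = 2, j = 3)
  expect_equal(tcrtyper:::forward_example(back$model, ex)$logits,
               tcrtyper:::forward_example(m, ex)$logits, tolerance = 1e-12)
})

test_that("imported backbone weights must match shapes", {
  m <- tiny_model("baseline")
  w <- list(word = m$params$backbone$word * 2)
  m2 <- import_backbone_weights(m, w)
  expect_equal(m2$params$backbone$word, m$params$backbone$word * 2)
  expect_error(import_backbone_weights(m, list(word = matrix(0, 2, 2))),
               "shape")
})
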