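# Synthetic VDJdb-dialect repertoire generator. Class signal can be planted
# in the CDR3 sequence (a per-class motif carried with configurable
# fidelity), in V/J gene usage (none / soft Dirichlet bias /
# deterministic), or both, so the sequence and gene routes of the
# classifiers can be dissociated experimentally. Contamination knobs inject
# rows that specific filter-cascade steps must remove.

#' Synthetic dataset configuration
#'
#' @param num_classes Number of epitope classes.
#' @param class_sizes Integer vector of per-class sizes (recycled); mix
#'   sizes above and below 100 to create easy- and hard-to-classify classes.
#' @param cdr3_length_range Inclusive range of CDR3 lengths.
#' @param motif_length Length of the per-class motif (when `motifs` is
#'   `NULL`, motifs are drawn at random, distinct across classes).
#' @param motifs Optional character vector of per-class motifs.
#' @param motif_fidelity Probability that a sample carries its class motif
#'   (0 removes all sequence-borne class signal).
#' @param gene_signal `"none"` (gene usage independent of class), `"soft"`
#'   (class-conditional Dirichlet-perturbed usage), or `"deterministic"`
#'   (each class has a fixed (V, J) pair).
#' @param gene_bias_concentration Dirichlet concentration for `"soft"`;
#'   smaller values give stronger class bias.
#' @param v_vocab_size,j_vocab_size Number of distinct V / J gene names
#'   (defaults 63 and 13, the typical scale of a filtered TRB dataset).
#' @param score_probs Probabilities of confidence scores 0..3 (default puts
#'   no mass on 0, so clean datasets pass the score filter).
#' @param contamination List with fractions `tra` (rows flipped to the TRA
#'   chain), `duplicate` (rows duplicated on the full dedup key), `score0`
#'   (rows forced to confidence score 0).
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(num_classes = 3L, class_sizes = 60L,
                             cdr3_length_range = c(10L, 16L),
                             motif_length = 4L, motifs = NULL,
                             motif_fidelity = 0.9,
                             gene_signal = c("none", "soft", "deterministic"),
                             gene_bias_concentration = 0.5,
                             v_vocab_size = 63L, j_vocab_size = 13L,
                             score_probs = c(0, 0.5, 0.3, 0.2),
                             contamination = list(tra = 0, duplicate = 0,
                                                  score0 = 0),
                             seed = 1L) {
  gene_signal <- match.arg(gene_signal)
  class_sizes <- rep_len(as.integer(class_sizes), num_classes)
  stopifnot(num_classes >= 2, all(class_sizes >= 1),
            motif_fidelity >= 0, motif_fidelity <= 1,
            motif_length < cdr3_length_range[1],
            length(score_probs) == 4, abs(sum(score_probs) - 1) < 1e-8,
            all(unlist(contamination) >= 0), all(unlist(contamination) <= 1))
  if (!is.null(motifs)) {
    stopifnot(length(motifs) == num_classes,
              all(nchar(motifs) < cdr3_length_range[1]))
  }
  structure(list(num_classes = as.integer(num_classes),
                 class_sizes = class_sizes,
                 cdr3_length_range = as.integer(cdr3_length_range),
                 motif_length = as.integer(motif_length), motifs = motifs,
                 motif_fidelity = motif_fidelity, gene_signal = gene_signal,
                 gene_bias_concentration = gene_bias_concentration,
                 v_vocab_size = as.integer(v_vocab_size),
                 j_vocab_size = as.integer(j_vocab_size),
                 score_probs = score_probs,
                 contamination = utils::modifyList(
                   list(tra = 0, duplicate = 0, score0 = 0), contamination),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_peptide <- function(n_chars) {
  paste(sample(AMINO_ACIDS, n_chars, replace = TRUE), collapse = "")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Generate a synthetic VDJdb-dialect table
#'
#' Records are drawn i.i.d. within each class: CDR3s are random residues
#' with the class motif planted at a random offset with probability
#' `motif_fidelity`; V/J genes follow the configured class-conditional
#' distributions; the epitope triple (species, gene, sequence) encodes the
#' class. Contamination rows are injected last. A fixed seed yields a
#' byte-identical table.
#'
#' @param config A [synthetic_config()].
#' @return data.frame in the VDJdb web-export dialect (see
#'   [vdjdb_column_map()]), with attribute `manifest` holding the ground
#'   truth (true class, motif carriage, contamination counts, generator
#'   config).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$num_classes
  v_names <- sprintf("TRBV%d", seq_len(config$v_vocab_size))
  j_names <- sprintf("TRBJ%d", seq_len(config$j_vocab_size))
  motifs <- config$motifs
  if (is.null(motifs)) {
    repeat {
      motifs <- vapply(seq_len(K), function(i) {
        random_peptide(config$motif_length)
      }, character(1))
      if (!anyDuplicated(motifs)) break
    }
  }
  epitopes <- vapply(seq_len(K), function(i) random_peptide(9L), character(1))

  v_probs <- matrix(1 / config$v_vocab_size, K, config$v_vocab_size)
  j_probs <- matrix(1 / config$j_vocab_size, K, config$j_vocab_size)
  if (config$gene_signal == "soft") {
    for (k in seq_len(K)) {
      v_probs[k, ] <- rdirichlet1(rep(config$gene_bias_concentration,
                                      config$v_vocab_size))
      j_probs[k, ] <- rdirichlet1(rep(config$gene_bias_concentration,
                                      config$j_vocab_size))
    }
  }
  det_v <- floor(seq(1, config$v_vocab_size, length.out = K))
  det_j <- ((seq_len(K) - 1) %% config$j_vocab_size) + 1

  n <- sum(config$class_sizes)
  class_of <- rep(seq_len(K), times = config$class_sizes)
  cdr3 <- character(n)
  motif_carried <- logical(n)
  v_gene <- character(n)
  j_gene <- character(n)
  lo <- config$cdr3_length_range[1]
  hi <- config$cdr3_length_range[2]
  for (i in seq_len(n)) {
    k <- class_of[i]
    len <- sample(lo:hi, 1)
    s <- random_peptide(len)
    if (runif(1) < config$motif_fidelity) {
      off <- sample.int(len - nchar(motifs[k]) + 1, 1)
      substr(s, off, off + nchar(motifs[k]) - 1) <- motifs[k]
      motif_carried[i] <- TRUE
    }
    cdr3[i] <- s
    if (config$gene_signal == "deterministic") {
      v_gene[i] <- v_names[det_v[k]]
      j_gene[i] <- j_names[det_j[k]]
    } else {
      v_gene[i] <- v_names[sample.int(config$v_vocab_size, 1,
                                      prob = v_probs[k, ])]
      j_gene[i] <- j_names[sample.int(config$j_vocab_size, 1,
                                      prob = j_probs[k, ])]
    }
  }

  tab <- data.frame(
    gene = rep("TRB", n),
    cdr3 = cdr3,
    v.segm = v_gene,
    j.segm = j_gene,
    mhc.a = rep("HLA-A*02:01", n),
    mhc.b = rep("B2M", n),
    mhc.class = rep("MHCI", n),
    species = rep("HomoSapiens", n),
    antigen.epitope = epitopes[class_of],
    antigen.gene = sprintf("gene%d", class_of),
    antigen.species = sprintf("SynthVirus%d", class_of),
    vdjdb.score = sample(0:3, n, replace = TRUE, prob = config$score_probs),
    check.names = FALSE, stringsAsFactors = FALSE
  )

  cont <- config$contamination
  n_tra <- floor(cont$tra * n)
  if (n_tra > 0) tab$gene[sample.int(n, n_tra)] <- "TRA"
  n_score0 <- floor(cont$score0 * n)
  if (n_score0 > 0) {
    eligible <- which(tab$gene == "TRB")
    pick <- eligible[sample.int(length(eligible), min(n_score0,
                                                      length(eligible)))]
    tab$vdjdb.score[pick] <- 0L
    n_score0 <- length(pick)
  }
  n_dup <- floor(cont$duplicate * n)
  if (n_dup > 0) {
    dup_rows <- tab[sample.int(n, n_dup, replace = FALSE), , drop = FALSE]
    tab <- rbind(tab, dup_rows)
  }
  rownames(tab) <- NULL

  attr(tab, "manifest") <- list(
    class_label = paste(sprintf("SynthVirus%d", class_of),
                        sprintf("gene%d", class_of), epitopes[class_of]),
    true_class = class_of,
    motifs = motifs,
    motif_carried = motif_carried,
    deterministic_v = if (config$gene_signal == "deterministic") {
      v_names[det_v]
    },
    deterministic_j = if (config$gene_signal == "deterministic") {
      j_names[det_j]
    },
    contamination_counts = list(tra = n_tra, score0 = n_score0,
                                duplicate = n_dup),
    config = config
  )
  tab
}

#' Write a generated table plus its ground-truth manifest
#'
#' @param tab A [generate()] result.
#' @param path Output TSV path; the manifest goes to `<path>.manifest.json`.
#' @export
write_synthetic <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- attr(tab, "manifest")
  manifest$config <- unclass(manifest$config)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

plugin_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  # Miller-Madow correction: the plug-in estimate is biased upward by about
  # (K_xy - K_x - K_y + 1) / 2n when many cells are sparsely observed
  bias <- (sum(tab > 0) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  list(plugin = mi, corrected = mi - bias)
}

#' Diagnostics on the planted class signal
#'
#' Reports empirical motif carriage per class and the plug-in mutual
#' information (nats) between the (V, J) gene pair and the class. Under
#' deterministic gene signal with distinct pairs, the MI equals the class
#' entropy; under `"none"` it approaches 0 as n grows.
#'
#' @param tab A [generate()] result (manifest attribute required).
#' @return List with `motif_carriage` (per-class fraction), `vj_class_mi`
#'   (plug-in estimate, nats), `vj_class_mi_corrected` (Miller-Madow
#'   bias-corrected, nats), `class_entropy` (nats).
#' @export
signal_check <- function(tab) {
  manifest <- attr(tab, "manifest")
  if (is.null(manifest)) stop("table lacks a generator manifest", call. = FALSE)
  n_orig <- length(manifest$true_class)
  base <- tab[seq_len(n_orig), , drop = FALSE]
  cls <- manifest$true_class
  carriage <- tapply(manifest$motif_carried, cls, mean)
  vj <- paste(base$v.segm, base$j.segm)
  p_cls <- as.numeric(table(cls)) / n_orig
  mi <- plugin_mi(vj, cls)
  list(
    motif_carriage = as.numeric(carriage),
    vj_class_mi = mi$plugin,
    vj_class_mi_corrected = mi$corrected,
    class_entropy = -sum(p_cls * log(p_cls))
  )
}
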