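# Evaluation suite: model-level metrics (weighted F1/precision/recall,
# balanced accuracy), epitope-level one-vs-rest AUROC with midrank tie
# handling, paired Wilcoxon comparison of per-class AUROC between models,
# the label-permutation chance control, and the easy/hard difficulty
# breakdown.

#' Confusion-matrix classification metrics
#'
#' Per-class precision, recall and F1 are computed from the confusion
#' matrix; weighted versions are support-weighted means over classes present
#' in the truth; balanced accuracy is the unweighted mean of per-class
#' recalls. Classes never predicted contribute precision 0 (not NaN).
#'
#' @param truth,pred Equal-length label vectors (any atomic type).
#' @return List with `weighted_f1`, `balanced_accuracy`,
#'   `weighted_precision`, `weighted_recall`, and `per_class` (data.frame).
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth, pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  w <- support[present] / sum(support[present])
  list(
    weighted_f1 = sum(w * f1[present]),
    balanced_accuracy = mean(recall[present]),
    weighted_precision = sum(w * precision[present]),
    weighted_recall = sum(w * recall[present]),
    per_class = data.frame(class = classes, support = as.integer(support),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall),
                           f1 = as.numeric(f1), stringsAsFactors = FALSE)
  )
}

# Binary AUROC by the Mann-Whitney rank identity; ties get midranks.
auroc_binary <- function(positive, scores) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest AUROC per class
#'
#' Each class's scores are compared against all other classes pooled as
#' negatives. Classes without both a positive and a negative are flagged
#' undefined (`NA`) and excluded from the mean.
#'
#' @param truth Label vector (length n).
#' @param scores n x C score matrix with class labels as column names (or
#'   columns aligned with `sort(unique(truth))`).
#' @return List with `per_class` (named numeric, `NA` where undefined),
#'   `mean_auroc`, and `undefined` (labels excluded from the mean).
#' @export
per_class_auroc <- function(truth, scores) {
  classes <- colnames(scores)
  if (is.null(classes)) {
    classes <- as.character(sort(unique(truth)))
    stopifnot(ncol(scores) == length(classes))
    colnames(scores) <- classes
  }
  stopifnot(nrow(scores) == length(truth))
  per_class <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    per_class[cl] <- auroc_binary(as.character(truth) == cl, scores[, cl])
  }
  defined <- !is.na(per_class)
  list(per_class = per_class,
       mean_auroc = mean(per_class[defined]),
       undefined = classes[!defined])
}

#' ROC curve points for one class
#'
#' Emits the (FPR, TPR) step curve as data for external plotting.
#'
#' @param positive Logical vector marking positives.
#' @param scores Numeric scores.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(positive, scores) {
  ord <- order(scores, decreasing = TRUE)
  positive <- positive[ord]
  scores <- scores[ord]
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  data.frame(
    threshold = c(Inf, scores[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / max(1, sum(!positive))),
    tpr = c(0, tp[last_of_tie] / max(1, sum(positive)))
  )
}

#' Paired Wilcoxon signed-rank comparison of per-class AUROC
#'
#' Two-sided signed-rank test on the per-class AUROC differences between two
#' models over the same class set. Zero differences are dropped (Wilcoxon's
#' original policy); the null distribution is exact for n <= 25 tie-free
#' differences and a normal approximation beyond.
#'
#' @param auroc_a,auroc_b Named per-class AUROC vectors over the same
#'   classes.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return List with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n_effective`, `method`, and `all_zero` flag.
#' @export
compare_models_wilcoxon <- function(auroc_a, auroc_b, exact_limit = 25L) {
  if (!is.null(names(auroc_a)) && !is.null(names(auroc_b))) {
    stopifnot(setequal(names(auroc_a), names(auroc_b)))
    auroc_b <- auroc_b[names(auroc_a)]
  }
  stopifnot(length(auroc_a) == length(auroc_b))
  d <- auroc_a - auroc_b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= exact_limit && !ties
  res <- suppressWarnings(
    wilcox.test(d, mu = 0, alternative = "two.sided", exact = use_exact,
                correct = FALSE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_effective = n,
       method = if (use_exact) "exact" else "normal approximation",
       all_zero = FALSE)
}

#' Label-permutation chance control
#'
#' Shuffles the labels with a seeded permutation and recomputes the mean
#' one-vs-rest AUROC; for any fixed score matrix this should land near 0.5,
#' demonstrating that reported performance is not an artifact of the
#' evaluation pipeline.
#'
#' @param truth Label vector.
#' @param scores n x C score matrix (see [per_class_auroc()]).
#' @param seed Integer seed; the identity permutation is used when
#'   `identity = TRUE`.
#' @param identity If `TRUE`, do not shuffle (reproduces the unshuffled
#'   report).
#' @return List with `mean_auroc`, `per_class`, and `permutation`.
#' @export
label_permutation_control <- function(truth, scores, seed = 1L,
                                      identity = FALSE) {
  perm <- if (identity) seq_along(truth) else {
    set.seed(seed)
    sample.int(length(truth))
  }
  shuffled <- truth[perm]
  res <- per_class_auroc(shuffled, scores)
  list(mean_auroc = res$mean_auroc, per_class = res$per_class,
       permutation = perm)
}

#' Easy/hard difficulty breakdown of per-class AUROC
#'
#' Unweighted AUROC means within the easy and hard groups plus an unpaired
#' rank-sum comparison across groups. If one group is empty the comparison
#' is skipped and flagged.
#'
#' @param per_class Named per-class AUROC vector.
#' @param difficulty Named vector mapping every class to `"easy"` /
#'   `"hard"` (see [categorize_difficulty()]).
#' @return List with `easy_mean`, `hard_mean`, `comparison` (rank-sum test
#'   or `NULL`), `skipped` flag.
#' @export
difficulty_report <- function(per_class, difficulty) {
  stopifnot(all(names(per_class) %in% names(difficulty)))
  diff <- difficulty[names(per_class)]
  easy <- per_class[diff == "easy" & !is.na(per_class)]
  hard <- per_class[diff == "hard" & !is.na(per_class)]
  easy_mean <- if (length(easy)) mean(easy) else NA_real_
  hard_mean <- if (length(hard)) mean(hard) else NA_real_
  if (length(easy) == 0 || length(hard) == 0) {
    return(list(easy_mean = easy_mean, hard_mean = hard_mean,
                comparison = NULL, skipped = TRUE))
  }
  cmp <- suppressWarnings(wilcox.test(easy, hard, alternative = "two.sided"))
  list(easy_mean = easy_mean, hard_mean = hard_mean,
       comparison = list(statistic = unname(cmp$statistic),
                         p_value = cmp$p.value),
       skipped = FALSE)
}

#' Full metrics report
#'
#' Bundles the model-level metrics, the per-class AUROC with mean, ROC
#' curve points per class, and (optionally) the difficulty breakdown.
#'
#' @param truth Label vector.
#' @param pred Predicted label vector.
#' @param scores n x C score matrix with class column names.
#' @param difficulty Optional named difficulty mapping.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(truth, pred, scores, difficulty = NULL) {
  cm <- classification_metrics(truth, pred)
  auc <- per_class_auroc(truth, scores)
  roc <- lapply(setNames(colnames(scores), colnames(scores)), function(cl) {
    roc_points(as.character(truth) == cl, scores[, cl])
  })
  out <- list(
    weighted_f1 = cm$weighted_f1,
    balanced_accuracy = cm$balanced_accuracy,
    weighted_precision = cm$weighted_precision,
    weighted_recall = cm$weighted_recall,
    per_class_auroc = auc$per_class,
    mean_auroc = auc$mean_auroc,
    undefined_auroc = auc$undefined,
    roc_points = roc,
    per_class = cm$per_class,
    difficulty = if (!is.null(difficulty)) {
      difficulty_report(auc$per_class, difficulty)
    }
  )
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("Metrics report\n  weighted F1: %.4f\n",
                     "  balanced accuracy: %.4f\n  weighted precision: %.4f\n",
                     "  weighted recall: %.4f\n  mean AUROC: %.4f (%d classes"),
              x$weighted_f1, x$balanced_accuracy, x$weighted_precision,
              x$weighted_recall, x$mean_auroc,
              sum(!is.na(x$per_class_auroc))))
  if (length(x$undefined_auroc)) {
    cat(sprintf(", %d undefined", length(x$undefined_auroc)))
  }
  cat(")\n")
  if (!is.null(x$difficulty) && !x$difficulty$skipped) {
    cat(sprintf("  AUROC easy/hard: %.4f / %.4f\n",
                x$difficulty$easy_mean, x$difficulty$hard_mean))
  }
  invisible(x)
}

#' Evaluate a trained model on a labelled example set
#'
#' @param model A trained [build_model()] result.
#' @param examples List of tokenized examples.
#' @param labels Integer class ids (1-based into `class_levels`).
#' @param class_levels Character class labels, in id order.
#' @param difficulty Optional named difficulty mapping.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, examples, labels, class_levels,
                           difficulty = NULL) {
  pr <- predict_classes(model, examples)
  colnames(pr$probs) <- class_levels
  metrics_report(class_levels[labels], class_levels[pr$pred], pr$probs,
                 difficulty = difficulty)
}

#' Serialize a metrics report to JSON
#'
#' @param report A [metrics_report()].
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
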