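#' Evaluation record
#'
#' Pairs true labels with full ranked predictions. `ranked` holds, per
#' sample, the class indices sorted by descending score; ties are broken
#' deterministically towards the lowest class index.
#'
#' @param true_labels Integer vector of true classes (1..K).
#' @param scores K x N score (or logit) matrix, or a ready-made N x K
#'   ranking matrix via `ranked`.
#' @param ranked Optional N x K integer matrix of rankings.
#' @return Object of class `eval_record`.
#' @export
eval_record <- function(true_labels, scores = NULL, ranked = NULL) {
  if (is.null(ranked)) {
    if (is.null(scores)) stop("provide scores or ranked")
    ranked <- t(apply(scores, 2, function(s) order(-s, seq_along(s))))
  }
  if (nrow(ranked) != length(true_labels)) {
    stop("one ranking per sample required")
  }
  structure(list(true = as.integer(true_labels), ranked = ranked),
            class = "eval_record")
}

#' Top-k accuracy
#'
#' Fraction of samples whose true class appears among the k
#' highest-scoring predictions.
#'
#' @param rec An [eval_record()].
#' @param k Positive integer no larger than the ranking length.
#' @return A fraction in [0, 1].
#' @export
top_k_accuracy <- function(rec, k = 1L) {
  if (!length(rec$true)) stop("empty evaluation record")
  if (k < 1 || k > ncol(rec$ranked)) stop("k out of range")
  topk <- rec$ranked[, seq_len(k), drop = FALSE]
  mean(vapply(seq_along(rec$true),
              function(i) rec$true[i] %in% topk[i, ], logical(1)))
}

#' Per-class precision, recall and F1
#'
#' Builds the top-1 confusion counts per class and derives precision,
#' recall, their harmonic mean F1, and the unweighted macro-F1. Classes
#' with no predicted and no actual instances get F1 = 0 and are flagged.
#'
#' @param rec An [eval_record()].
#' @param n_classes Number of classes; default inferred.
#' @return List of class `class_scores` with a per-class data frame
#'   (`class`, `TP`, `FP`, `FN`, `precision`, `recall`, `f1`, `flagged`)
#'   and `macro_f1`.
#' @export
per_class_scores <- function(rec, n_classes = ncol(rec$ranked)) {
  pred <- rec$ranked[, 1]
  tab <- data.frame(class = seq_len(n_classes), TP = 0L, FP = 0L, FN = 0L)
  for (c in seq_len(n_classes)) {
    tab$TP[c] <- sum(pred == c & rec$true == c)
    tab$FP[c] <- sum(pred == c & rec$true != c)
    tab$FN[c] <- sum(pred != c & rec$true == c)
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  tab$precision <- safe_div(tab$TP, tab$TP + tab$FP)
  tab$recall <- safe_div(tab$TP, tab$TP + tab$FN)
  tab$f1 <- safe_div(2 * tab$precision * tab$recall,
                     tab$precision + tab$recall)
  tab$flagged <- (tab$TP + tab$FP + tab$FN) == 0
  if (any(tab$flagged)) {
    warning("class(es) with no predicted and no actual instances: F1 set to 0")
  }
  structure(list(table = tab, macro_f1 = mean(tab$f1)),
            class = "class_scores")
}

#' Aggregate repeated runs
#'
#' Mean and sample standard deviation per metric over repeated runs with
#' different seeds (the five-seed mean +/- SD reporting convention).
#'
#' @param values Numeric vector (one metric) or matrix/data frame with one
#'   column per metric and one row per run.
#' @return List of class `run_summary` with `mean`, `sd`, `runs`.
#' @export
aggregate_runs <- function(values) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) < 2) {
    stop("need at least 2 runs; use the values directly for single runs")
  }
  structure(list(mean = colMeans(values), sd = apply(values, 2, sd),
                 runs = values),
            class = "run_summary")
}

#' Evaluate a model on a dataset split
#'
#' Runs inference with the fused teacher head (or the student classifier)
#' on one split and returns the full ranked predictions.
#'
#' @param model A `narm_teacher` or `narm_student`.
#' @param data A loaded dataset from [load_dataset()].
#' @param split Split name (`"train"`, `"val"`, `"test"`).
#' @param noise Optional [noise_spec()] applied to the evaluation images
#'   (for robustness sweeps); `NULL` evaluates clean.
#' @return An [eval_record()].
#' @export
evaluate_model <- function(model, data, split = "test", noise = NULL) {
  idx <- which(data$split == split)
  x <- data$images[, , , idx, drop = FALSE]
  if (!is.null(noise) && noise$sigma > 0) x <- inject_gaussian_noise(x, noise)
  logits <- if (inherits(model, "narm_teacher")) {
    predict_teacher(model, x)$logits
  } else {
    predict_student(model, x)
  }
  eval_record(data$labels[idx], scores = logits)
}
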