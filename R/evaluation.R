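# Performance metrics: error rate, one-vs-all ROC and precision-recall
# curves with their areas, and cross-validated aggregation over repeated
# stratified holdouts.

#' Misclassification rate
#'
#' @param predicted,truth Equal-length class-index vectors.
#' @return Fraction misclassified in `[0, 1]`.
#' @export
error_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stop("`predicted` and `truth` must be equal-length, non-empty",
         call. = FALSE)
  }
  mean(predicted != truth)
}

# Binary ROC curve for numeric scores: returns fpr/tpr points (including
# the (0,0) and (1,1) endpoints, tie groups collapsed) and the trapezoidal
# AUC, which equals the Mann-Whitney pair statistic with ties counted 1/2.
binary_roc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(diff(scores[ord]) != 0, TRUE) # last element of each tie group
  tpr <- c(0, tp[keep] / sum(positive))
  fpr <- c(0, fp[keep] / sum(!positive))
  list(curve = data.frame(fpr = fpr, tpr = tpr),
       auc = trapezoid_area(fpr, tpr))
}

# Binary precision-recall curve with the step-wise (average-precision)
# area: AUC = sum over threshold steps of (recall gain) * precision.
binary_pr <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  n_pred <- seq_along(pos)
  keep <- c(diff(scores[ord]) != 0, TRUE)
  precision <- (tp / n_pred)[keep]
  recall <- (tp / sum(pos))[keep]
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision), auc = auc)
}

#' One-vs-all ROC curves and AUCs
#'
#' Scores class `c` by probability column `c` against the binary indicator
#' `truth == c`; the AUC is the trapezoidal area (equal to the Mann-Whitney
#' pair statistic), and the mean AUC is the unweighted average over the
#' classes present in `truth`. Classes absent from `truth` are skipped with
#' a warning.
#'
#' @param scores N x M row-stochastic probability matrix.
#' @param truth Length-N vector of 1-based true classes.
#' @return List with `per_class` (per-class list of `curve` data frame and
#'   `auc`) and `mean_auc`.
#' @export
roc_auc_one_vs_all <- function(scores, truth) {
  one_vs_all(scores, truth, binary_roc)
}

#' One-vs-all precision-recall curves and AUCs
#'
#' Precision-recall pairs at every distinct score threshold, with the
#' step-wise (non-interpolated, average-precision) area convention; the
#' mean AUC is the unweighted average over classes present.
#'
#' @inheritParams roc_auc_one_vs_all
#' @return List with `per_class` and `mean_auc`.
#' @export
precision_recall_one_vs_all <- function(scores, truth) {
  one_vs_all(scores, truth, binary_pr)
}

one_vs_all <- function(scores, truth, fn) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(truth)) {
    stop("`scores` rows must match `truth` length", call. = FALSE)
  }
  m <- ncol(scores)
  per_class <- vector("list", m)
  for (cl in seq_len(m)) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) {
      warning(sprintf(
        "class %d absent from truth (or truth is single-class); skipped", cl))
      next
    }
    per_class[[cl]] <- fn(scores[, cl], pos)
  }
  aucs <- vapply(per_class, function(x) if (is.null(x)) NA_real_ else x$auc,
                 numeric(1))
  list(per_class = per_class, auc = aucs, mean_auc = mean(aucs, na.rm = TRUE))
}

#' Cross-validated model evaluation
#'
#' Trains and evaluates the classifier on each split from
#' [stratified_holdout()], scoring test tiles with the T-sample MC-dropout
#' posterior mean, and aggregates accuracy, error rate and one-vs-all
#' ROC/PR AUCs as mean and standard deviation across folds. `classes`
#' restricts the dataset to a subset of classes before splitting (e.g. a
#' binary tumour-vs-stroma task).
#'
#' @param dataset A labelled [patch_dataset()].
#' @param k Number of stratified holdout repeats.
#' @param mod_config A [model_config()] (its `n_classes` must match the
#'   number of classes evaluated).
#' @param tr_config A [train_config()].
#' @param T Variational samples for test scoring.
#' @param classes Optional integer vector of class indices to keep.
#' @param seed Integer seed for the splits.
#' @return An object of class `eval_result`: list with `per_fold` (data
#'   frame of accuracy, error rate, mean AUCs per fold), `summary` (mean and
#'   sd), and the per-class AUC matrices `roc_auc`, `pr_auc`.
#' @export
cross_validate <- function(dataset, k, mod_config, tr_config, T = 50,
                           classes = NULL, seed = 1) {
  if (!is.null(classes)) {
    keep <- patch_labels(dataset) %in% classes
    patches <- dataset$patches[keep]
    # relabel into 1..length(classes), preserving order of `classes`
    patches <- lapply(patches, function(p) {
      p$label <- match(p$label, classes)
      p
    })
    catalog <- class_catalog(dataset$catalog$names[classes],
                            dataset$catalog$colors[classes, , drop = FALSE])
    dataset <- patch_dataset(patches, catalog)
  }
  splits <- stratified_holdout(dataset, k, seed)
  m <- length(dataset$catalog$names)
  stopifnot(mod_config$n_classes == m)
  folds <- vector("list", k)
  roc_mat <- matrix(NA_real_, k, m)
  pr_mat <- matrix(NA_real_, k, m)
  for (i in seq_len(k)) {
    sp <- splits[[i]]
    model <- build_classifier(mod_config, seed = derive_seed(seed, 10L + i))
    tr <- tr_config
    tr$seed <- derive_seed(seed, 20L + i)
    model <- train_classifier(model, dataset_subset(dataset, sp$train_ids), tr)
    test <- dataset_subset(dataset, sp$test_ids)
    X <- stack_pixels(test$patches, mod_config$input_size)
    probs <- mc_proba_batch(model, X, n_patches(test), T,
                            seed = derive_seed(seed, 30L + i),
                            eval_batch = tr$eval_batch,
                            uncertainty = FALSE)$mean
    truth <- patch_labels(test)
    pred <- max.col(probs, ties.method = "first")
    roc <- roc_auc_one_vs_all(probs, truth)
    pr <- precision_recall_one_vs_all(probs, truth)
    roc_mat[i, ] <- roc$auc
    pr_mat[i, ] <- pr$auc
    folds[[i]] <- data.frame(fold = i,
                             n_train = length(sp$train_ids),
                             n_test = length(sp$test_ids),
                             accuracy = mean(pred == truth),
                             error_rate = error_rate(pred, truth),
                             mean_roc_auc = roc$mean_auc,
                             mean_pr_auc = pr$mean_auc)
  }
  per_fold <- do.call(rbind, folds)
  metrics <- c("accuracy", "error_rate", "mean_roc_auc", "mean_pr_auc")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(mm) mean(per_fold[[mm]]),
                                      numeric(1)),
                        sd = vapply(metrics, function(mm) stats::sd(per_fold[[mm]]),
                                    numeric(1)))
  structure(list(per_fold = per_fold, summary = summary,
                 roc_auc = roc_mat, pr_auc = pr_mat,
                 pr_area_convention = "step-wise (average precision)"),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d folds\n", nrow(x$per_fold)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
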