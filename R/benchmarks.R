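# Reduced-scale benchmark harnesses on synthetic data. These fix the
# package's desk-scale study conditions — 24x24-pixel tiles, a 4-class
# generator with one confusable pair, and a small trunk — so the
# qualitative behaviour of the method (uncertainty-guided acquisition,
# noise-robust training, confident-misclassification mislabel detection)
# can be demonstrated end-to-end in minutes on one CPU. The vignette
# discusses what these scales do and do not show.

#' Reduced-scale model configuration
#'
#' A small trunk (8 filters, one residual block) over 24 x 24 tiles used by
#' the synthetic benchmarks; all other settings (dropout 0.5, two 32-unit
#' dropout layers, dual heads) match the full-scale defaults.
#'
#' @param M Number of classes.
#' @param size Tile side in pixels (default 24).
#' @return A [model_config()].
#' @export
toy_model_config <- function(M = 4, size = 24) {
  model_config(n_classes = M, input_size = c(size, size), filters = 8,
               n_blocks = 1)
}

#' Reduced-scale training configuration
#'
#' At toy scale the validation split is small (tens of tiles), so its
#' accuracy moves in coarse jumps; a longer plateau patience than the
#' full-scale default keeps the learning-rate rule from freezing training
#' mid-flight.
#'
#' @param epochs Training epochs (default 20).
#' @param val_fraction Validation fraction (default 0.1).
#' @param seed Integer seed.
#' @return A [train_config()] with `lr_patience = 8`.
#' @export
toy_train_config <- function(epochs = 20, val_fraction = 0.1, seed = 1) {
  train_config(epochs = epochs, lr_patience = 8, val_fraction = val_fraction,
               seed = seed)
}

#' Planted-noise mislabel benchmark
#'
#' For each seed and each planted-noise rate `p_m`: generates a balanced
#' 4-class synthetic training set and an independent test set, corrupts
#' `p_m` percent of the training labels, trains the classifier on the
#' corrupted data, then (a) measures clean-test accuracy from the MC
#' posterior mean and (b) runs the mislabel detector at the same `p_m` on
#' the training records and scores it against the planted ground truth.
#'
#' @param p_m_values Noise percentages to evaluate (default 0/10/30/50).
#' @param n_seeds Independent replicates (default 3).
#' @param M Classes (default 4).
#' @param n_train_per_class,n_test_per_class Tiles per class (defaults
#'   120 / 50).
#' @param size Tile side in pixels (default 24).
#' @param epochs Training epochs per run (default 20).
#' @param T Variational samples for scoring (default 25).
#' @param seed Master seed.
#' @return Data frame with one row per (seed, p_m): `test_accuracy`,
#'   `sensitivity`, `specificity`, `recall`, `n_candidates`, `n_planted`.
#' @export
mislabel_benchmark <- function(p_m_values = c(0, 10, 30, 50), n_seeds = 3,
                               M = 4, n_train_per_class = 120,
                               n_test_per_class = 50, size = 24, epochs = 20,
                               T = 25, seed = 1) {
  cfg <- toy_model_config(M, size)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    train <- generate_dataset(M, n_train_per_class, size = size,
                              seed = derive_seed(seed, s, 1L))
    test <- generate_dataset(M, n_test_per_class, size = size,
                             seed = derive_seed(seed, s, 2L),
                             id_prefix = "test/")
    test_X <- stack_pixels(test$patches, cfg$input_size)
    test_y <- patch_labels(test)
    for (pm in p_m_values) {
      noisy <- plant_label_noise(train, pm, seed = derive_seed(seed, s, 3L, pm))
      model <- build_classifier(cfg, seed = derive_seed(seed, s, 4L, pm))
      model <- train_classifier(
        model, noisy$dataset,
        toy_train_config(epochs = epochs, seed = derive_seed(seed, s, 5L, pm)))
      probs <- mc_proba_batch(model, test_X, length(test_y), T,
                              seed = derive_seed(seed, s, 6L, pm),
                              uncertainty = FALSE)$mean
      acc <- mean(max.col(probs, ties.method = "first") == test_y)
      sens <- spec_ <- rec <- NA_real_
      n_cand <- NA_integer_
      if (pm > 0) {
        recs <- score_dataset(model, noisy$dataset, T = T,
                              seed = derive_seed(seed, s, 7L, pm))
        report <- identify_mislabelled(recs, pm)
        ev <- evaluate_identification(report, noisy$planted, recs$id)
        sens <- ev$sensitivity; spec_ <- ev$specificity; rec <- ev$recall
        n_cand <- ev$n_candidates
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, p_m = pm, test_accuracy = acc, sensitivity = sens,
        specificity = spec_, recall = rec, n_candidates = n_cand,
        n_planted = length(noisy$planted))
    }
  }
  do.call(rbind, rows)
}

#' Reduced-scale active-learning benchmark
#'
#' Compares acquisition strategies on a synthetic 4-class dataset whose
#' classes 1 and 2 are confusable (blended generative parameters), across
#' independent seeds. Each run starts from a 40-per-class stratified seed
#' set and acquires 160 tiles per step until the pool is exhausted; the
#' per-trace quality score is the size-normalised area under the
#' accuracy-vs-size curve ([trace_auc()]).
#'
#' @param strategies Strategies to compare (default random and entropy-H).
#' @param n_seeds Independent replicates (default 3).
#' @param M Classes (default 4).
#' @param n_train_per_class,n_test_per_class Tiles per class (defaults
#'   150 / 50, so the pool holds 600 tiles and a trace has 4 steps).
#' @param size Tile side in pixels (default 24).
#' @param confusable_pair,confusability Passed to [generate_dataset()]
#'   (defaults: classes 1-2 at 0.6).
#' @param epochs_per_step Training epochs per step (default 30, so every
#'   step trains to convergence at this scale; per-step models use the
#'   toy-scale plateau patience of 8, see [toy_train_config()]).
#' @param T Variational samples for acquisition scoring (default 20).
#' @param seed Master seed.
#' @return List with `traces` (all traces, with `al_seed` column), `auc`
#'   (per seed x strategy) and `mean_auc` (named per-strategy means).
#' @export
al_benchmark <- function(strategies = c("random", "entropy_H"), n_seeds = 3,
                         M = 4, n_train_per_class = 150, n_test_per_class = 50,
                         size = 24, confusable_pair = c(1, 2),
                         confusability = 0.6, epochs_per_step = 30, T = 20,
                         seed = 1) {
  cfg <- toy_model_config(M, size)
  traces <- list()
  aucs <- list()
  for (s in seq_len(n_seeds)) {
    train <- generate_dataset(M, n_train_per_class, size = size,
                              confusable_pair = confusable_pair,
                              confusability = confusability,
                              seed = derive_seed(seed, s, 1L))
    test <- generate_dataset(M, n_test_per_class, size = size,
                             confusable_pair = confusable_pair,
                             confusability = confusability,
                             seed = derive_seed(seed, s, 2L),
                             id_prefix = "test/")
    for (strat in strategies) {
      acq <- acquisition_config(strategy = strat, T = T,
                                epochs_per_step = epochs_per_step,
                                seed = derive_seed(seed, s, 3L))
      step_tr <- toy_train_config(epochs = epochs_per_step,
                                  val_fraction = 0.3)
      tr <- run_active_learning(train, test, acq, cfg, step_tr)
      tr$al_seed <- s
      traces[[length(traces) + 1L]] <- tr
      aucs[[length(aucs) + 1L]] <- data.frame(al_seed = s, strategy = strat,
                                              auc = trace_auc(tr))
    }
  }
  traces <- do.call(rbind, traces)
  aucs <- do.call(rbind, aucs)
  mean_auc <- tapply(aucs$auc, aucs$strategy, mean)
  list(traces = traces, auc = aucs, mean_auc = mean_auc)
}
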