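# Pool-based active learning: uncertainty-driven acquisition of unlabelled
# tiles, the per-trace loop, and the multi-seed experiment harness comparing
# Random, entropy-H and BALD acquisition.

#' Acquisition configuration
#'
#' @param strategy One of `"random"`, `"entropy_H"`, `"bald"`.
#' @param seed_per_class Tiles per class in the initial labelled seed set
#'   (default 40).
#' @param step_size Tiles acquired per step (default 160).
#' @param T Variational samples used when scoring the pool (default 50).
#' @param n_inits Fresh model initialisations per configuration in the
#'   experiment harness (default 8).
#' @param n_splits Dataset splits in the experiment harness (default 3).
#' @param epochs_per_step Training epochs at each step (default 100).
#' @param seed Integer master seed.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(strategy = c("random", "entropy_H", "bald"),
                               seed_per_class = 40, step_size = 160, T = 50,
                               n_inits = 8, n_splits = 3,
                               epochs_per_step = 100, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(seed_per_class >= 1, step_size >= 1, T >= 1,
            n_inits >= 1, n_splits >= 1, epochs_per_step >= 1)
  structure(list(strategy = strategy,
                 seed_per_class = as.integer(seed_per_class),
                 step_size = as.integer(step_size), T = as.integer(T),
                 n_inits = as.integer(n_inits), n_splits = as.integer(n_splits),
                 epochs_per_step = as.integer(epochs_per_step),
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Labelled-set size at a given acquisition step
#'
#' Steps are 0-indexed: step 0 is the stratified seed set of
#' `M * seed_per_class` tiles, and each later step adds `step_size` tiles,
#' capped by the pool size. With 8 classes, 40 seed tiles per class and
#' steps of 160, steps 0/7/15 hold 320/1440/2720 tiles.
#'
#' @param step Step index (>= 0).
#' @param M Number of classes.
#' @param config An [acquisition_config()].
#' @param pool_total Total number of tiles available for labelling.
#' @return Integer labelled-set size.
#' @export
schedule_size <- function(step, M, config, pool_total) {
  stopifnot(all(step >= 0))
  as.integer(pmin(M * config$seed_per_class + step * config$step_size,
                  pool_total))
}

#' Number of steps needed to exhaust the pool
#'
#' Counts step 0; the final step may be partial (it adds only the tiles
#' that remain).
#'
#' @inheritParams schedule_size
#' @return Integer step count.
#' @export
schedule_total_steps <- function(M, config, pool_total) {
  seed_total <- M * config$seed_per_class
  if (pool_total <= seed_total) return(1L)
  1L + as.integer(ceiling((pool_total - seed_total) / config$step_size))
}

#' Select the k most uncertain records
#'
#' Sorts uncertainty records by the chosen measure in descending order and
#' returns the ids of the top `k`; ties are broken by lexicographic id, so
#' selection is stable.
#'
#' @param records Data frame from [score_dataset()].
#' @param measure `"entropy_H"` or `"bald"`.
#' @param k Number of ids to select.
#' @return Character vector of ids.
#' @export
select_top_k <- function(records, measure = c("entropy_H", "bald"), k) {
  measure <- match.arg(measure)
  vals <- switch(measure, entropy_H = records$H, bald = records$BALD)
  if (k > nrow(records)) {
    warning(sprintf("k = %d exceeds the %d available records; returning all",
                    k, nrow(records)))
    k <- nrow(records)
  }
  ord <- order(-vals, records$id, method = "radix")
  records$id[ord][seq_len(k)]
}

#' Select k pool ids uniformly at random
#'
#' Uniform sampling without replacement, reproducible under the seed and
#' independent of the input ordering of `pool_ids`.
#'
#' @param pool_ids Character vector of candidate ids.
#' @param k Number to draw (`k <= length(pool_ids)`).
#' @param rng_seed Integer seed.
#' @return Character vector of k distinct ids.
#' @export
select_random <- function(pool_ids, k, rng_seed) {
  if (k > length(pool_ids)) {
    stop(sprintf("k = %d exceeds pool size %d", k, length(pool_ids)),
         call. = FALSE)
  }
  with_seed(rng_seed, sample(sort(pool_ids, method = "radix"), k))
}

#' Run one active-learning trace
#'
#' Step 0 trains on a class-stratified seed set of `seed_per_class` tiles
#' per class. Each later step retrains from a fresh initialisation on the
#' labelled set grown by `step_size` tiles chosen by the acquisition
#' strategy — uncertainty scores are computed on the remaining pool only —
#' until the pool is exhausted (the final step may acquire fewer). Test
#' accuracy at each step is measured with the MC-dropout posterior mean.
#'
#' @param full_train Fully labelled [patch_dataset()] acting as the pool.
#' @param test Labelled [patch_dataset()] for per-step evaluation; must not
#'   share ids with `full_train`.
#' @param config An [acquisition_config()].
#' @param mod_config A [model_config()].
#' @param tr_config A [train_config()]; its `epochs` are overridden by
#'   `config$epochs_per_step` and a 0.3 validation fraction is the
#'   recommended setting at active-learning scale.
#' @return An `active_learning_trace`: data frame with columns `step`
#'   (0-based), `size`, `accuracy`, `strategy`.
#' @export
run_active_learning <- function(full_train, test, config, mod_config,
                                tr_config = train_config(
                                  epochs = config$epochs_per_step,
                                  val_fraction = 0.3)) {
  stopifnot(inherits(config, "acquisition_config"))
  labels <- patch_labels(full_train)
  if (anyNA(labels)) stop("pool must be fully labelled", call. = FALSE)
  if (length(intersect(patch_ids(full_train), patch_ids(test))) > 0L) {
    stop("test set shares ids with the training pool", call. = FALSE)
  }
  m <- mod_config$n_classes
  ids <- patch_ids(full_train)
  pool_total <- length(ids)
  if (pool_total < m * config$seed_per_class) {
    stop("pool smaller than the initial seed set", call. = FALSE)
  }

  # stratified step-0 seed set
  labelled <- with_seed(derive_seed(config$seed, 0L), {
    unlist(lapply(split(ids, labels), function(cls_ids) {
      sample(sort(cls_ids, method = "radix"), config$seed_per_class)
    }), use.names = FALSE)
  })
  pool <- setdiff(ids, labelled)

  test_X <- stack_pixels(test$patches, mod_config$input_size)
  test_y <- patch_labels(test)
  n_steps <- schedule_total_steps(m, config, pool_total)
  out <- vector("list", n_steps)

  for (step in seq_len(n_steps) - 1L) {
    model <- build_classifier(mod_config,
                              seed = derive_seed(config$seed, 1000L + step))
    tr <- tr_config
    tr$epochs <- config$epochs_per_step
    tr$seed <- derive_seed(config$seed, 2000L + step)
    model <- train_classifier(model, dataset_subset(full_train, labelled), tr)
    probs <- mc_proba_batch(model, test_X, length(test_y), config$T,
                            seed = derive_seed(config$seed, 3000L + step),
                            eval_batch = tr$eval_batch,
                            uncertainty = FALSE)$mean
    acc <- mean(max.col(probs, ties.method = "first") == test_y)
    out[[step + 1L]] <- data.frame(step = step, size = length(labelled),
                                   accuracy = acc,
                                   strategy = config$strategy,
                                   stringsAsFactors = FALSE)
    if (length(pool) == 0L) break
    k <- min(config$step_size, length(pool))
    new_ids <- if (config$strategy == "random") {
      select_random(pool, k, derive_seed(config$seed, 4000L + step))
    } else {
      recs <- score_dataset(model, dataset_subset(full_train, pool),
                            T = config$T,
                            seed = derive_seed(config$seed, 5000L + step),
                            eval_batch = tr$eval_batch)
      select_top_k(recs,
                   measure = if (config$strategy == "bald") "bald"
                             else "entropy_H", k = k)
    }
    labelled <- c(labelled, new_ids)
    pool <- setdiff(pool, new_ids)
  }
  trace <- do.call(rbind, out)
  class(trace) <- c("active_learning_trace", class(trace))
  trace
}

#' Area under an accuracy-vs-size trace
#'
#' Trapezoidal area of test accuracy against labelled-set size, normalised
#' by the size range, so the value is a size-averaged accuracy in `[0, 1]`.
#' Used to compare acquisition strategies.
#'
#' @param trace An `active_learning_trace` (or data frame with `size` and
#'   `accuracy`).
#' @return Scalar normalised area.
#' @export
trace_auc <- function(trace) {
  ord <- order(trace$size)
  s <- trace$size[ord]; a <- trace$accuracy[ord]
  if (length(s) < 2L) return(a[1])
  trapezoid_area(s, a) / (s[length(s)] - s[1])
}

#' Multi-seed active-learning experiment harness
#'
#' Repeats [run_active_learning()] for each strategy across `n_inits`
#' model initialisations and `n_splits` dataset splits (all derived from
#' `config$seed`) and averages the traces, mirroring the
#' pre-initialisation protocol used when comparing acquisition functions.
#'
#' @param full_train,test As in [run_active_learning()].
#' @param strategies Character vector of strategies to compare.
#' @param config An [acquisition_config()] (its `strategy` field is
#'   overridden per run; `n_inits` controls repeats — here each repeat uses
#'   a distinct derived seed covering both initialisation and split).
#' @param mod_config,tr_config As in [run_active_learning()].
#' @return A list with `traces` (all per-repeat traces, with a `repeat_id`
#'   column), `mean_trace` (per-strategy, per-step averages) and `auc`
#'   (per-strategy mean of [trace_auc()]).
#' @export
al_compare <- function(full_train, test,
                       strategies = c("random", "entropy_H", "bald"),
                       config = acquisition_config(), mod_config,
                       tr_config = train_config(
                         epochs = config$epochs_per_step, val_fraction = 0.3)) {
  n_rep <- config$n_inits * config$n_splits
  traces <- list()
  for (strat in strategies) {
    for (r in seq_len(n_rep)) {
      cfg <- config
      cfg$strategy <- strat
      cfg$seed <- derive_seed(config$seed, r)
      tr <- run_active_learning(full_train, test, cfg, mod_config, tr_config)
      tr$repeat_id <- r
      traces[[length(traces) + 1L]] <- tr
    }
  }
  traces <- do.call(rbind, traces)
  mean_trace <- aggregate(accuracy ~ strategy + step + size, data = traces,
                          FUN = mean)
  auc <- vapply(split(traces, traces$strategy), function(df) {
    mean(vapply(split(df, df$repeat_id), trace_auc, numeric(1)))
  }, numeric(1))
  list(traces = traces, mean_trace = mean_trace, auc = auc)
}

#' Write active-learning traces as CSV
#'
#' @param traces Data frame of traces.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats aggregate
NULL
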