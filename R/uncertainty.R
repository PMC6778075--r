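# Monte-Carlo variational-dropout inference and the two uncertainty
# measures: predictive entropy H (total uncertainty) and BALD mutual
# information (epistemic uncertainty).

#' Construct a predictive posterior from MC samples
#'
#' A `predictive_posterior` holds the T x M matrix of per-pass class
#' probabilities (row t is one variational dropout pass) and its row
#' average, the model's final class distribution for the tile.
#'
#' @param samples T x M matrix, each row a probability vector.
#' @return An object of class `predictive_posterior` with fields `samples`,
#'   `mean` and `T`.
#' @export
predictive_posterior <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("at least one MC sample is required", call. = FALSE)
  if (any(samples < -1e-9) || any(abs(rowSums(samples) - 1) > 1e-6)) {
    stop("each sample row must be a probability vector summing to 1",
         call. = FALSE)
  }
  structure(list(samples = samples, mean = colMeans(samples),
                 T = nrow(samples)),
            class = "predictive_posterior")
}

#' @export
print.predictive_posterior <- function(x, ...) {
  cat(sprintf("<predictive_posterior> T=%d, M=%d, H=%.4f nats, BALD=%.4f nats\n",
              x$T, length(x$mean), entropy_H(x), bald(x)))
  invisible(x)
}

# Per-pass dropout unit masks for one variational weight sample.
mc_masks <- function(config, seed = NULL) {
  draw <- function() {
    h <- config$head_hidden_units
    r <- config$dropout_rate
    list(m1 = (stats::runif(h) >= r) / (1 - r),
         m2 = (stats::runif(h) >= r) / (1 - r))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Monte-Carlo dropout prediction for one tile
#'
#' Runs `T` stochastic forward passes (dropout active; batch-norm frozen)
#' and averages the per-pass class probabilities, approximating the
#' predictive posterior mean. Each pass draws one per-unit dropout mask per
#' hidden layer — one sample of the variational weight distribution — so two
#' identical tiles scored under the same seed receive identical posteriors.
#'
#' @param model A trained `tile_classifier`.
#' @param patch An [image_patch()] or H x W x 3 pixel array.
#' @param T Number of variational samples (default 50).
#' @param seed Optional integer seed; pass `t` uses a substream derived from
#'   `(seed, t)`. When `NULL` the current RNG stream is used.
#' @return A [predictive_posterior()].
#' @export
mc_predict <- function(model, patch, T = 50, seed = NULL) {
  stopifnot(inherits(model, "tile_classifier"))
  T <- stopifnot_scalar_int(T, "T", min = 1)
  cfg <- model$config
  X <- stack_pixels(list(patch), cfg$input_size)
  tf <- trunk_forward(model$params, X, cfg$input_size[1], cfg$input_size[2],
                      1L, training = FALSE)
  samples <- matrix(0, T, cfg$n_classes)
  for (t in seq_len(T)) {
    masks <- mc_masks(cfg, if (is.null(seed)) NULL else derive_seed(seed, t))
    hf <- head_forward(model$params, tf$feats, cfg$dropout_rate,
                       mode = "mc", masks = masks)
    samples[t, ] <- hf$final
  }
  predictive_posterior(samples)
}

#' Predictive entropy H
#'
#' Shannon entropy (natural log, nats) of the predictive posterior mean,
#' with the convention `0 * log 0 = 0`. Measures total predictive
#' uncertainty: both epistemic (model) and aleatoric (data) components.
#' Ranges from 0 (one-hot) to `log M` (uniform).
#'
#' @param posterior A [predictive_posterior()] or a probability vector.
#' @return Entropy in nats.
#' @examples
#' entropy_H(rep(1/8, 8)) # log(8)
#' @export
entropy_H <- function(posterior) {
  p <- if (inherits(posterior, "predictive_posterior")) posterior$mean
       else as.numeric(posterior)
  shannon_entropy(p)
}

#' BALD mutual information
#'
#' Mutual information between the predicted label and the model weights:
#' the entropy of the posterior mean minus the mean entropy of the per-pass
#' predictions. High when the passes disagree confidently (epistemic
#' uncertainty); near zero when every pass returns the same — possibly flat
#' — distribution (pure aleatoric uncertainty). Tiny negative floating-point
#' results are clipped to 0, since mutual information is non-negative.
#'
#' @param posterior A [predictive_posterior()].
#' @return BALD in nats; always `0 <= BALD <= entropy_H(posterior)`.
#' @export
bald <- function(posterior) {
  stopifnot(inherits(posterior, "predictive_posterior"))
  mean_row_h <- mean(apply(posterior$samples, 1L, shannon_entropy))
  max(entropy_H(posterior) - mean_row_h, 0)
}

#' Predicted class of a posterior
#'
#' Argmax of the posterior mean; exact ties are broken toward the lowest
#' class index.
#'
#' @param posterior A [predictive_posterior()].
#' @return 1-based class index.
#' @export
classify <- function(posterior) {
  stopifnot(inherits(posterior, "predictive_posterior"))
  which.max(posterior$mean)
}

# MC-mean probabilities for a stacked pixel matrix: trunk evaluated once per
# eval_batch chunk, T seeded per-pass unit-mask head passes shared across
# chunks. Returns list(mean = N x M, H, bald) when `uncertainty` is TRUE.
mc_proba_batch <- function(model, X, N, T, seed = 0, eval_batch = 128,
                           uncertainty = TRUE) {
  cfg <- model$config
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  hw <- H * W
  mask_sets <- lapply(seq_len(T), function(t) mc_masks(cfg, derive_seed(seed, t)))
  mean_p <- matrix(0, N, cfg$n_classes)
  ent_sum <- numeric(N)
  starts <- seq(1L, N, by = eval_batch)
  for (s in starts) {
    e <- min(s + eval_batch - 1L, N)
    nb <- e - s + 1L
    rows <- ((s - 1L) * hw + 1L):(e * hw)
    tf <- trunk_forward(model$params, X[rows, , drop = FALSE], H, W, nb,
                        training = FALSE)
    acc <- matrix(0, nb, cfg$n_classes)
    for (t in seq_len(T)) {
      hf <- head_forward(model$params, tf$feats, cfg$dropout_rate,
                         mode = "mc", masks = mask_sets[[t]])
      acc <- acc + hf$final
      if (uncertainty) {
        pl <- hf$final * log(pmax(hf$final, 1e-300))
        ent_sum[s:e] <- ent_sum[s:e] - rowSums(pl)
      }
    }
    mean_p[s:e, ] <- acc / T
  }
  if (!uncertainty) return(list(mean = mean_p))
  pl <- mean_p * log(pmax(mean_p, 1e-300))
  Hv <- -rowSums(pl)
  list(mean = mean_p, H = Hv, bald = pmax(Hv - ent_sum / T, 0))
}

#' Score every tile of a dataset with MC-dropout uncertainty
#'
#' Runs batched Monte-Carlo inference over the dataset and returns one
#' record per patch, in dataset order: predicted class, predictive entropy
#' `H` (nats), `H_normalized = H / log(M)` and `BALD` (nats), plus the
#' assigned label when known. The per-pass dropout masks are derived from
#' `seed`, so scoring is fully reproducible and identical tiles receive
#' identical records.
#'
#' @param model A trained `tile_classifier`.
#' @param dataset A [patch_dataset()] (labels may be missing).
#' @param T Number of variational samples (default 50).
#' @param seed Integer seed for the MC mask stream.
#' @param eval_batch Tiles per evaluation chunk (default 128).
#' @return A data frame with columns `id`, `true_label`, `predicted`, `H`,
#'   `H_normalized`, `BALD`.
#' @export
score_dataset <- function(model, dataset, T = 50, seed = 0, eval_batch = 128) {
  stopifnot(inherits(model, "tile_classifier"),
            inherits(dataset, "patch_dataset"))
  T <- stopifnot_scalar_int(T, "T", min = 1)
  n <- n_patches(dataset)
  m <- model$config$n_classes
  if (n == 0L) {
    return(data.frame(id = character(0), true_label = integer(0),
                      predicted = integer(0), H = numeric(0),
                      H_normalized = numeric(0), BALD = numeric(0)))
  }
  X <- stack_pixels(dataset$patches, model$config$input_size)
  res <- mc_proba_batch(model, X, n, T, seed = seed, eval_batch = eval_batch)
  data.frame(id = patch_ids(dataset),
             true_label = patch_labels(dataset),
             predicted = max.col(res$mean, ties.method = "first"),
             H = res$H,
             H_normalized = res$H / log(m),
             BALD = res$bald,
             stringsAsFactors = FALSE)
}

#' Write / read uncertainty records as CSV
#'
#' @param records Data frame from [score_dataset()].
#' @param path CSV file path.
#' @return `write_uncertainty_records` invisibly returns `path`;
#'   `read_uncertainty_records` returns the data frame.
#' @export
write_uncertainty_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uncertainty_records
#' @export
read_uncertainty_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
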