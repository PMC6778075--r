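# The dropout-regularised dual-head convolutional classifier: configuration,
# construction, training with plateau-based learning-rate reduction, and
# single-pass prediction.

#' Model architecture configuration
#'
#' The classifier is a compact residual convolutional trunk (3x3
#' convolutions, batch normalisation, a max-pooled stem, identity skip
#' connections with 2x2 max-pooling after each block, global average
#' pooling) followed by two
#' dropout-bearing fully connected layers with `head_hidden_units` units.
#' The first feeds an auxiliary softmax head, the second the final softmax
#' head. Dropout (default rate 0.5, so on average half the units of each
#' hidden layer are switched off per pass) is what makes Monte-Carlo
#' variational inference possible at prediction time.
#'
#' @param n_classes Number of classes M (>= 2).
#' @param input_size Length-2 integer vector, input height and width in
#'   pixels (default `c(128, 128)`); must be divisible by
#'   `2^(n_blocks + 1)`. Tiles of other sizes are bilinearly resized on the
#'   way in.
#' @param filters Convolutional trunk width (channels per layer).
#' @param n_blocks Number of residual blocks (trunk depth knob).
#' @param dropout_rate Dropout probability in `(0, 1)` applied to both
#'   hidden fully connected layers.
#' @param head_hidden_units Units in each of the two hidden FC layers
#'   (default 32).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes, input_size = c(128, 128), filters = 16,
                         n_blocks = 2, dropout_rate = 0.5,
                         head_hidden_units = 32) {
  stopifnot(n_classes >= 2, dropout_rate > 0, dropout_rate < 1,
            filters >= 1, n_blocks >= 1, head_hidden_units >= 1)
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  input_size <- as.integer(input_size)
  # one downsampling after the stem plus one per residual block
  if (any(input_size %% 2L^(n_blocks + 1L) != 0L)) {
    stop("`input_size` must be divisible by 2^(n_blocks + 1)", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes), input_size = input_size,
                 filters = as.integer(filters), n_blocks = as.integer(n_blocks),
                 dropout_rate = dropout_rate,
                 head_hidden_units = as.integer(head_hidden_units)),
            class = "model_config")
}

#' Training configuration
#'
#' Mini-batch Adam training with a validation-accuracy plateau rule: the
#' learning rate is multiplied by `lr_reduce_factor` whenever validation
#' accuracy has not improved for `lr_patience` consecutive epochs. An
#' internal stratified validation split of `val_fraction` is carved out of
#' the training data (0.1 for ordinary training; 0.3 is recommended in
#' active-learning mode, where the labelled set is small).
#'
#' @param epochs Number of training epochs (default 200; 100 is typical per
#'   active-learning step).
#' @param train_batch Training mini-batch size (default 32).
#' @param eval_batch Evaluation batch size (default 128).
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param lr_reduce_factor Multiplicative plateau reduction (default 0.1).
#' @param lr_patience Epochs without validation improvement before a
#'   reduction (default 5).
#' @param val_fraction Fraction held out for validation, in `(0, 1)`.
#' @param final_weight,aux_weight Loss weights for the final and auxiliary
#'   heads; must sum to 1 (defaults 0.9 / 0.1).
#' @param seed Integer seed controlling the validation split, shuffling and
#'   training-time dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, train_batch = 32, eval_batch = 128,
                         learning_rate = 1e-3, lr_reduce_factor = 0.1,
                         lr_patience = 5, val_fraction = 0.1,
                         final_weight = 0.9, aux_weight = 0.1, seed = 1) {
  stopifnot(epochs >= 1, train_batch >= 1, eval_batch >= 1,
            learning_rate > 0, lr_reduce_factor > 0, lr_reduce_factor < 1,
            lr_patience >= 1, val_fraction > 0, val_fraction < 1)
  if (abs(final_weight + aux_weight - 1) > 1e-12) {
    stop("`final_weight` + `aux_weight` must equal 1", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 train_batch = as.integer(train_batch),
                 eval_batch = as.integer(eval_batch),
                 learning_rate = learning_rate,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience = as.integer(lr_patience),
                 val_fraction = val_fraction,
                 final_weight = final_weight, aux_weight = aux_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) classifier
#'
#' Initialises all trunk and head parameters (He-scaled Gaussian weights,
#' unit batch-norm scales) under the given seed.
#'
#' @param config A [model_config()].
#' @param seed Integer initialisation seed.
#' @return An object of class `tile_classifier` with fields `config`,
#'   `params` (the learned parameters), `n_params`, `history` (per-epoch
#'   training record once trained) and `trained`.
#' @export
build_classifier <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  params <- init_params(config, seed)
  structure(list(config = config, params = params,
                 n_params = count_params(params),
                 history = NULL, trained = FALSE, init_seed = as.integer(seed)),
            class = "tile_classifier")
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat(sprintf(
    "<tile_classifier> M=%d, input %dx%d, %d filters x %d blocks, %d parameters%s\n",
    x$config$n_classes, x$config$input_size[1], x$config$input_size[2],
    x$config$filters, x$config$n_blocks, x$n_params,
    if (x$trained) sprintf(" (trained, %d epochs)", nrow(x$history)) else
      " (untrained)"))
  invisible(x)
}

# Bilinearly resize an H x W x 3 pixel array (0..255) to target dims.
resize_pixels <- function(px, h, w) {
  d <- dim(px)
  if (d[1] == h && d[2] == w) return(px)
  img <- EBImage::resize(EBImage::Image(px / 255, colormode = "Color"),
                         w = h, h = w) # EBImage's first dim matches our rows
  clamp(EBImage::imageData(img) * 255, 0, 255)
}

# Stack patches into the engine's (H*W*N) x 3 matrix of normalised pixels,
# resizing to the model input size where needed.
stack_pixels <- function(patches, input_size) {
  H <- input_size[1]; W <- input_size[2]
  n <- length(patches)
  X <- matrix(0, H * W * n, 3L)
  hw <- H * W
  for (i in seq_len(n)) {
    px <- patches[[i]]
    if (inherits(px, "image_patch")) px <- px$pixels
    if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
      stop(sprintf("patch %d does not have 3 channels", i), call. = FALSE)
    }
    px <- resize_pixels(px, H, W)
    X[((i - 1L) * hw + 1L):(i * hw), ] <- matrix(px, hw, 3L) / 255 - 0.5
  }
  X
}

#' Weighted dual-head cross-entropy loss
#'
#' Natural-log categorical cross-entropy of each head at the true label,
#' combined as `weights[1] * CE(final) + weights[2] * CE(aux)`. Probabilities
#' are clamped at 1e-12 so the loss is always finite. The loss is zero
#' exactly when both heads are one-hot at the true label.
#'
#' @param final_probs,aux_probs Row-stochastic probability vectors of length
#'   M from the final and auxiliary heads.
#' @param true_label 1-based true class index.
#' @param weights Length-2 non-negative weights summing to 1 (default
#'   `c(0.9, 0.1)`).
#' @return Non-negative scalar loss in nats.
#' @examples
#' dual_head_loss(rep(1/8, 8), rep(1/8, 8), 1)    # log(8)
#' @export
dual_head_loss <- function(final_probs, aux_probs, true_label,
                           weights = c(0.9, 0.1)) {
  stopifnot(length(final_probs) == length(aux_probs),
            true_label >= 1, true_label <= length(final_probs),
            abs(sum(weights) - 1) < 1e-9)
  for (p in list(final_probs, aux_probs)) {
    if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
      stop("head outputs must be probability vectors summing to 1",
           call. = FALSE)
    }
  }
  ce <- function(p) -log(max(p[true_label], 1e-12))
  weights[1] * ce(final_probs) + weights[2] * ce(aux_probs) + 0
}

# Stratified validation index split; returns list(train_idx, val_idx).
val_split <- function(labels, val_fraction, seed) {
  with_seed(seed, {
    val_idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      nv <- if (length(ix) >= 2L) max(1L, round(val_fraction * length(ix))) else 0L
      if (nv > 0L) sample(ix, nv) else integer(0)
    }), use.names = FALSE)
    list(train_idx = setdiff(seq_along(labels), val_idx), val_idx = val_idx)
  })
}

# Deterministic (dropout-off, frozen batch-norm) final-head probabilities
# for a stacked pixel matrix, evaluated in eval_batch chunks.
predict_proba_det <- function(model, X, N, eval_batch = 128) {
  cfg <- model$config
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  hw <- H * W
  out <- matrix(0, N, cfg$n_classes)
  starts <- seq(1L, N, by = eval_batch)
  for (s in starts) {
    e <- min(s + eval_batch - 1L, N)
    rows <- ((s - 1L) * hw + 1L):(e * hw)
    nb <- e - s + 1L
    tf <- trunk_forward(model$params, X[rows, , drop = FALSE], H, W, nb,
                        training = FALSE)
    hf <- head_forward(model$params, tf$feats, cfg$dropout_rate, mode = "det")
    out[s:e, ] <- hf$final
  }
  colnames(out) <- NULL
  out
}

#' Train the classifier
#'
#' Mini-batch Adam training of the dual-head network on a labelled dataset,
#' with an internal stratified validation split and plateau-based
#' learning-rate reduction (rate multiplied by `lr_reduce_factor` whenever
#' validation accuracy fails to improve for `lr_patience` epochs). Tiles
#' whose size differs from the model input are bilinearly resized. Training
#' is deterministic given the configuration seeds.
#'
#' @param model A [build_classifier()] result.
#' @param train_data A fully labelled [patch_dataset()] with at least two
#'   classes present.
#' @param config A [train_config()].
#' @return The trained `tile_classifier`, with `history` a data frame of
#'   per-epoch `epoch`, `lr`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`.
#' @export
train_classifier <- function(model, train_data, config = train_config()) {
  stopifnot(inherits(model, "tile_classifier"),
            inherits(train_data, "patch_dataset"),
            inherits(config, "train_config"))
  labels <- patch_labels(train_data)
  if (anyNA(labels)) stop("all training patches must be labelled", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  cfg <- model$config
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  hw <- H * W
  X <- stack_pixels(train_data$patches, cfg$input_size)
  n <- length(labels)

  sp <- val_split(labels, config$val_fraction, derive_seed(config$seed, 1L))
  tr_idx <- sp$train_idx; va_idx <- sp$val_idx

  params <- model$params
  opt <- adam_init(params)
  lr <- config$learning_rate
  best_val <- -Inf
  wait <- 0L
  hist <- vector("list", config$epochs)

  rows_of <- function(ids) {
    as.vector(outer(seq_len(hw), (ids - 1L) * hw, "+"))
  }
  eval_split <- function(idx) {
    if (length(idx) == 0L) return(c(NA_real_, NA_real_))
    loss <- 0; acc <- 0
    starts <- seq(1L, length(idx), by = config$eval_batch)
    for (s in starts) {
      ids <- idx[s:min(s + config$eval_batch - 1L, length(idx))]
      tf <- trunk_forward(params, X[rows_of(ids), , drop = FALSE], H, W,
                          length(ids), training = FALSE)
      hf <- head_forward(params, tf$feats, cfg$dropout_rate, mode = "det")
      loss <- loss + sum(config$final_weight *
                           cross_entropy_rows(hf$final, labels[ids]) +
                         config$aux_weight *
                           cross_entropy_rows(hf$aux, labels[ids]))
      acc <- acc + sum(max.col(hf$final, ties.method = "first") == labels[ids])
    }
    c(loss / length(idx), acc / length(idx))
  }

  set.seed(derive_seed(config$seed, 2L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_acc <- 0
    starts <- seq(1L, length(ord), by = config$train_batch)
    for (s in starts) {
      ids <- ord[s:min(s + config$train_batch - 1L, length(ord))]
      res <- nn_loss_grads(params, X[rows_of(ids), , drop = FALSE],
                           labels[ids], cfg,
                           final_weight = config$final_weight,
                           aux_weight = config$aux_weight, mode = "train")
      params <- res$params # batch-norm running statistics were updated
      st <- adam_step(params, res$grads, opt, lr)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + res$loss * length(ids)
      ep_acc <- ep_acc + res$acc * length(ids)
    }
    va <- eval_split(va_idx)
    hist[[ep]] <- data.frame(epoch = ep, lr = lr,
                             train_loss = ep_loss / length(ord),
                             train_acc = ep_acc / length(ord),
                             val_loss = va[1], val_acc = va[2])
    if (!is.na(va[2]) && va[2] > best_val + 1e-12) {
      best_val <- va[2]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$lr_patience) {
        lr <- lr * config$lr_reduce_factor
        wait <- 0L
      }
    }
  }
  model$params <- params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model$train_seed <- config$seed
  model
}

#' One forward pass of the classifier
#'
#' With `stochastic = FALSE` dropout is disabled and repeated calls return
#' identical probability vectors. With `stochastic = TRUE` the dropout masks
#' stay active (one variational weight sample), so repeated calls differ.
#' Batch-normalisation always uses its frozen running statistics: dropout is
#' the only stochastic element of a prediction-time pass.
#'
#' @param model A `tile_classifier`.
#' @param patch An [image_patch()] (or H x W x 3 pixel array, 0..255).
#' @param stochastic Keep dropout active?
#' @return Named length-M probability vector from the final head.
#' @export
predict_single_pass <- function(model, patch, stochastic = FALSE) {
  stopifnot(inherits(model, "tile_classifier"))
  X <- stack_pixels(list(patch), model$config$input_size)
  cfg <- model$config
  tf <- trunk_forward(model$params, X, cfg$input_size[1], cfg$input_size[2],
                      1L, training = FALSE)
  hf <- head_forward(model$params, tf$feats, cfg$dropout_rate,
                     mode = if (stochastic) "train" else "det")
  p <- drop(hf$final)
  names(p) <- NULL
  p
}

#' Save / load a classifier checkpoint
#'
#' Standard R serialisation of the full classifier object (parameters,
#' configuration and training history).
#'
#' @param model A `tile_classifier`.
#' @param path File path.
#' @return `save_classifier` invisibly returns `path`; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)
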