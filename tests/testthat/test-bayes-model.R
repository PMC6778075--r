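# The dual-head dropout classifier: loss identities, gradients, dropout
# behaviour and the training loop contract.

test_that("dual-head loss reproduces its closed-form identities", {
  onehot <- c(1, 0, 0, 0, 0, 0, 0, 0)
  uniform <- rep(1 / 8, 8)
  expect_equal(dual_head_loss(onehot, onehot, 1), 0, tolerance = 1e-10)
  expect_equal(dual_head_loss(uniform, uniform, 3), log(8), tolerance = 1e-10)
  expect_equal(dual_head_loss(uniform, onehot, 1), 0.9 * log(8),
               tolerance = 1e-10)
  # loss is positive whenever either head is off the true label
  expect_gt(dual_head_loss(onehot, uniform, 1), 0)
  expect_error(dual_head_loss(c(0.5, 0.6), c(0.5, 0.5), 1), "summing to 1")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  cfg <- model_config(n_classes = 3, input_size = c(8, 8), filters = 4,
                      n_blocks = 1)
  params <- tilebayes:::init_params(cfg, 7)
  N <- 3
  X <- matrix(rnorm(8 * 8 * N * 3), 8 * 8 * N, 3)
  y <- c(1L, 2L, 3L)
  masks <- list(m1 = rep(1, 32), m2 = rep(1, 32))
  res <- tilebayes:::nn_loss_grads(params, X, y, cfg, mode = "mc",
                                   masks = masks)
  loss_fn <- function(p) {
    tilebayes:::nn_loss_grads(p, X, y, cfg, mode = "mc", masks = masks)$loss
  }
  modify <- function(tree, path, idx, delta) {
    if (length(path) == 0) {
      tree[idx] <- tree[idx] + delta
      return(tree)
    }
    tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], idx, delta)
    tree
  }
  leafpaths <- list(c("stem", "W", 1), c("stem", "bn", "g"),
                    c("blocks", 1, "c1", 5), c("blocks", 1, "bn1", "g"),
                    c("blocks", 1, "c2", 9), c("blocks", 1, "bn2", "b"),
                    c("fc1", "W"), c("aux", "W"), c("fc2", "W"),
                    c("fin", "W"))
  eps <- 1e-5
  for (lp in leafpaths) {
    leaf <- params
    for (k in lp) leaf <- leaf[[k]]
    g_an <- res$grads
    for (k in lp) g_an <- g_an[[k]]
    for (j in sample(length(leaf), min(3, length(leaf)))) {
      g_num <- (loss_fn(modify(params, lp, j, eps)) -
                  loss_fn(modify(params, lp, j, -eps))) / (2 * eps)
      expect_lt(abs(g_num - g_an[j]) /
                  max(1e-6, abs(g_num) + abs(g_an[j])), 1e-5)
    }
  }
})

test_that("an 8-class 128px model builds with both heads row-stochastic", {
  cfg <- model_config(n_classes = 8, input_size = c(128, 128))
  model <- build_classifier(cfg, seed = 1)
  expect_true(model$n_params > 0)
  X <- matrix(rnorm(128 * 128 * 2 * 3, sd = 0.1), 128 * 128 * 2, 3)
  tf <- tilebayes:::trunk_forward(model$params, X, 128, 128, 2L,
                                  training = FALSE)
  hf <- tilebayes:::head_forward(model$params, tf$feats, 0.5, mode = "det")
  expect_equal(rowSums(hf$final), c(1, 1), tolerance = 1e-6)
  expect_equal(rowSums(hf$aux), c(1, 1), tolerance = 1e-6)
})

test_that("dropout zeroes about half the units and drives pass-to-pass variation", {
  cfg <- toy_model_config(4, 24)
  zero_frac <- replicate(500, {
    m <- tilebayes:::mc_masks(cfg)
    mean(c(m$m1, m$m2) == 0)
  })
  expect_equal(mean(zero_frac), 0.5, tolerance = 0.05)

  fit <- get_toy_fit()
  patch <- fit$test$patches[[1]]
  det1 <- predict_single_pass(fit$model, patch, stochastic = FALSE)
  det2 <- predict_single_pass(fit$model, patch, stochastic = FALSE)
  expect_identical(det1, det2)
  expect_equal(sum(det1), 1, tolerance = 1e-6)
  set.seed(1)
  st1 <- predict_single_pass(fit$model, patch, stochastic = TRUE)
  st2 <- predict_single_pass(fit$model, patch, stochastic = TRUE)
  expect_false(identical(st1, st2))
})

test_that("training records full history with exact x0.1 plateau drops", {
  fit <- get_toy_fit()
  h <- fit$model$history
  expect_identical(nrow(h), 20L)
  expect_true(all(diff(h$lr) <= 0))
  drops <- h$lr[-1] / h$lr[-nrow(h)]
  expect_true(all(abs(drops - 1) < 1e-12 | abs(drops - 0.1) < 1e-12))
})

test_that("the toy task is learned to high training and held-out accuracy", {
  fit <- get_toy_fit()
  cfg <- fit$model$config
  train_probs <- tilebayes:::predict_proba_det(
    fit$model, tilebayes:::stack_pixels(fit$train$patches, cfg$input_size),
    n_patches(fit$train))
  expect_gte(mean(max.col(train_probs, ties.method = "first") ==
                    patch_labels(fit$train)), 0.95)
  test_probs <- tilebayes:::predict_proba_det(
    fit$model, tilebayes:::stack_pixels(fit$test$patches, cfg$input_size),
    n_patches(fit$test))
  expect_gte(mean(max.col(test_probs, ties.method = "first") ==
                    patch_labels(fit$test)), 0.9)
})

test_that("training is reproducible and rejects degenerate inputs", {
  train <- generate_dataset(2, 20, size = 16, seed = 41)
  cfg <- model_config(2, input_size = c(16, 16), filters = 4, n_blocks = 1)
  tc <- toy_train_config(epochs = 2, seed = 9)
  m1 <- train_classifier(build_classifier(cfg, seed = 5), train, tc)
  m2 <- train_classifier(build_classifier(cfg, seed = 5), train, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$fin$W, m2$params$fin$W)

  single <- dataset_subset(train, patch_ids(train)[patch_labels(train) == 1])
  expect_error(train_classifier(build_classifier(cfg, 1), single, tc),
               "two classes")
  expect_error(predict_single_pass(m1, array(0, dim = c(16, 16, 2))),
               "3 channels")
})

test_that("tiles of a different size are resized into the model input", {
  fit <- get_toy_fit()
  big <- generate_dataset(4, 1, size = 36, seed = 51)
  p <- predict_single_pass(fit$model, big$patches[[1]])
  expect_length(p, 4L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})
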