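# Shared fixtures, built in code and memoised so expensive training runs
# happen once per test session. All scales here are the package's
# reduced-scale study conditions (see the methods vignette).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A dataset of n-per-class 1x1-pixel dummy patches: cheap carrier for
# split/schedule arithmetic that never touches the pixels.
dummy_dataset <- function(M, n_per_class) {
  catalog <- class_catalog(sprintf("c%02d", seq_len(M)))
  patches <- vector("list", M * n_per_class)
  k <- 0L
  for (ci in seq_len(M)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      patches[[k]] <- image_patch(array(0L, dim = c(1, 1, 3)),
                                  id = sprintf("c%02d/%04d", ci, i),
                                  label = ci)
    }
  }
  patch_dataset(patches, catalog)
}

# Easy (fully separable) 4-class fit: model trained to convergence plus the
# train/test datasets.
get_toy_fit <- function() {
  memo("toy_fit", {
    train <- generate_dataset(4, 120, size = 24, seed = 11)
    test <- generate_dataset(4, 50, size = 24, seed = 12, id_prefix = "test/")
    model <- build_classifier(toy_model_config(4, 24), seed = 1)
    model <- train_classifier(model, train, toy_train_config(epochs = 20,
                                                             seed = 2))
    list(model = model, train = train, test = test)
  })
}

# Fit on data whose classes 1 and 2 are confusable (aleatoric overlap).
get_confusable_fit <- function() {
  memo("confusable_fit", {
    train <- generate_dataset(4, 100, size = 24, confusable_pair = c(1, 2),
                              confusability = 0.6, seed = 21)
    test <- generate_dataset(4, 50, size = 24, confusable_pair = c(1, 2),
                             confusability = 0.6, seed = 22,
                             id_prefix = "test/")
    model <- build_classifier(toy_model_config(4, 24), seed = 3)
    model <- train_classifier(model, train, toy_train_config(epochs = 15,
                                                             seed = 4))
    list(model = model, train = train, test = test)
  })
}

get_mislabel_bench <- function() {
  memo("mislabel_bench", mislabel_benchmark(n_seeds = 3, seed = 1))
}

get_al_bench <- function() {
  memo("al_bench", al_benchmark(n_seeds = 3, seed = 1))
}
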