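# Tile containers, directory-tree IO and stratified holdout splits.

test_that("image_patch validates its pixel grid and label", {
  p <- image_patch(array(128L, dim = c(4, 5, 3)), id = "a", label = 2L)
  expect_s3_class(p, "image_patch")
  expect_identical(dim(p$pixels), c(4L, 5L, 3L))
  expect_error(image_patch(array(300, dim = c(2, 2, 3)), id = "a"),
               "0, 255")
  expect_error(image_patch(array(0L, dim = c(2, 2, 3)), id = ""),
               "non-empty")
  # grayscale matrices are replicated to 3 channels
  g <- image_patch(matrix(7L, 3, 3), id = "g")
  expect_identical(dim(g$pixels), c(3L, 3L, 3L))
})

test_that("patch_dataset enforces unique ids and catalog-bounded labels", {
  cat2 <- class_catalog(c("a", "b"))
  mk <- function(id, lab) image_patch(array(0L, dim = c(1, 1, 3)), id, lab)
  expect_error(patch_dataset(list(mk("x", 1L), mk("x", 2L)), cat2), "unique")
  expect_error(patch_dataset(list(mk("x", 3L)), cat2), "labels outside")
  ds <- patch_dataset(list(mk("x", 1L), mk("y", 2L), mk("z", NA)), cat2)
  expect_identical(n_patches(ds), 3L)
  expect_identical(class_counts(ds), c(a = 1L, b = 1L))
})

test_that("tile trees load with lexicographic ids and per-class labels", {
  root <- withr::local_tempdir()
  catalog <- class_catalog(c("alpha", "beta"))
  for (cls in c("alpha", "beta")) {
    dir.create(file.path(root, cls), recursive = TRUE)
  }
  set.seed(5)
  for (cls in c("alpha", "beta")) {
    for (f in c("t2.png", "t1.png", "t3.png")) {
      img <- EBImage::Image(array(runif(16 * 16 * 3), c(16, 16, 3)),
                            colormode = "Color")
      EBImage::writeImage(img, file.path(root, cls, f))
    }
  }
  ds <- load_tile_dataset(root, catalog)
  expect_identical(n_patches(ds), 6L)
  expect_identical(patch_labels(ds), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(patch_ids(ds),
                   c("alpha/t1.png", "alpha/t2.png", "alpha/t3.png",
                     "beta/t1.png", "beta/t2.png", "beta/t3.png"))

  # empty class directories give an empty dataset, classes intact
  root2 <- withr::local_tempdir()
  dir.create(file.path(root2, "alpha"))
  dir.create(file.path(root2, "beta"))
  ds2 <- load_tile_dataset(root2, catalog)
  expect_identical(n_patches(ds2), 0L)
  expect_identical(length(ds2$catalog$names), 2L)

  # missing class directory errors with the class name
  expect_error(load_tile_dataset(root2, class_catalog(c("alpha", "gamma"))),
               "gamma")
})

test_that("writing a dataset and reloading round-trips ids, labels, pixels", {
  catalog <- class_catalog(c("one", "two"))
  set.seed(9)
  patches <- list()
  for (ci in 1:2) {
    for (i in 1:3) {
      patches[[length(patches) + 1L]] <- image_patch(
        array(sample(0:255, 12 * 12 * 3, replace = TRUE), c(12, 12, 3)),
        id = sprintf("%s/p%d.png", c("one", "two")[ci], i), label = ci)
    }
  }
  ds <- patch_dataset(patches, catalog)
  root <- withr::local_tempdir()
  write_tile_dataset(ds, root)
  back <- load_tile_dataset(root, catalog)
  expect_identical(patch_ids(back), patch_ids(ds))
  expect_identical(patch_labels(back), patch_labels(ds))
  for (i in seq_along(patches)) {
    expect_identical(back$patches[[i]]$pixels, ds$patches[[i]]$pixels)
  }
})

test_that("stratified holdout reproduces the printed per-class counts", {
  ds <- dummy_dataset(8, 625)
  splits <- stratified_holdout(ds, k = 10, seed = 42)
  expect_length(splits, 10L)
  for (sp in splits[c(1, 5, 10)]) {
    expect_length(sp$test_ids, 504L)
    expect_length(sp$train_ids, 4496L)
    test_classes <- table(patch_labels(dataset_subset(ds, sp$test_ids)))
    expect_true(all(test_classes == 63L))
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  }
})

test_that("holdout sizes use ceiling rounding and respect the seed", {
  ds <- dummy_dataset(2, 10)
  splits <- stratified_holdout(ds, k = 2, seed = 7)
  expect_length(splits[[1]]$test_ids, 10L)  # ceil(10/2) = 5 per class
  expect_length(splits[[1]]$train_ids, 10L)
  again <- stratified_holdout(ds, k = 2, seed = 7)
  expect_identical(sort(splits[[2]]$test_ids), sort(again[[2]]$test_ids))
  other <- stratified_holdout(ds, k = 2, seed = 8)
  expect_false(identical(sort(splits[[1]]$test_ids),
                         sort(other[[1]]$test_ids)))
  expect_error(stratified_holdout(dummy_dataset(2, 3), k = 4, seed = 1),
               "fewer than k")
})

test_that("splits serialise to a two-column table and back", {
  ds <- dummy_dataset(2, 6)
  sp <- stratified_holdout(ds, k = 3, seed = 1)[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, path)
  back <- read_split(path)
  expect_setequal(back$train_ids, sp$train_ids)
  expect_setequal(back$test_ids, sp$test_ids)
})
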