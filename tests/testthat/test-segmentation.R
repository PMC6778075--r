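# Tiling, slide segmentation, rendering and class-area statistics.

# Oracle classifier: looks up the ground-truth mask under each tile and
# returns a one-hot vector for the tile's majority class.
mask_oracle <- function(mask, tile_size, n_classes) {
  function(patch) {
    r <- attr(patch, "row")
    cc <- attr(patch, "col")
    rows <- ((r - 1) * tile_size + 1):(r * tile_size)
    cols <- ((cc - 1) * tile_size + 1):(cc * tile_size)
    counts <- tabulate(mask[rows, cols], nbins = n_classes)
    out <- numeric(n_classes)
    out[which.max(counts)] <- 1
    out
  }
}

test_that("tiling drops edge remainders and counts floor-division tiles", {
  sl <- array(0L, dim = c(100, 100, 3))
  tiles <- tile_image(sl, 50)
  expect_length(tiles, 4L)
  expect_identical(attr(tiles, "grid_dim"), c(2L, 2L))

  sl2 <- array(0L, dim = c(170, 120, 3))
  tiles2 <- tile_image(sl2, 50)
  expect_length(tiles2, 6L)
  expect_identical(attr(tiles2, "grid_dim"), c(3L, 2L))
  expect_identical(dim(tiles2[[1]]$pixels), c(50L, 50L, 3L))
  expect_error(tile_image(array(0L, dim = c(40, 60, 3)), 50), "exceeds")
})

test_that("tiles partition the retained slide area in row-major order", {
  set.seed(13)
  sl <- array(sample(0:255, 60 * 90 * 3, replace = TRUE), c(60, 90, 3))
  tiles <- tile_image(sl, 30)
  expect_length(tiles, 6L)
  # reassemble and compare against the original
  rebuilt <- array(NA_integer_, dim = dim(sl))
  for (p in tiles) {
    r <- attr(p, "row"); cc <- attr(p, "col")
    rebuilt[((r - 1) * 30 + 1):(r * 30), ((cc - 1) * 30 + 1):(cc * 30), ] <-
      p$pixels
  }
  expect_identical(rebuilt, sl)
  expect_identical(attr(tiles[[2]], "row"), 1L)  # second tile: row 1, col 2
  expect_identical(attr(tiles[[2]], "col"), 2L)
})

test_that("an oracle classifier recovers the layout's areas exactly", {
  lay <- slide_layout(120, 120, data.frame(
    x = c(1, 31, 1), y = c(1, 1, 91), w = c(30, 90, 120),
    h = c(90, 90, 30), class = c(1L, 2L, 3L)))
  sl <- generate_slide(lay, seed = 7, specs = default_texture_specs(3))
  map <- segment_slide(sl$slide, mask_oracle(sl$mask, 30, 3), tile_size = 30,
                       n_classes = 3)
  expect_identical(dim(map$grid), c(4L, 4L))
  # layout aligned to the 30px grid: tile-majority equals the true class
  true_frac <- 100 * tabulate(sl$mask, nbins = 3) / length(sl$mask)
  expect_equal(as.numeric(map$class_area), true_frac, tolerance = 1e-12)
  expect_equal(sum(map$class_area), 100, tolerance = 1e-9)
  # single-region layout gives a constant grid
  lay1 <- slide_layout(60, 60, data.frame(x = 1, y = 1, w = 60, h = 60,
                                          class = 2))
  sl1 <- generate_slide(lay1, seed = 8, specs = default_texture_specs(3))
  map1 <- segment_slide(sl1$slide, mask_oracle(sl1$mask, 30, 3),
                        tile_size = 30, n_classes = 3)
  expect_true(all(map1$grid == 2L))
  expect_equal(as.numeric(map1$class_area), c(0, 100, 0))
})

test_that("class-area statistics conserve 100% and report absent classes", {
  map <- structure(list(grid = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                        uncertainty = matrix(0, 2, 2), tile_size = 10,
                        n_classes = 4), class = "segmentation_map")
  area <- class_area_statistics(map)
  expect_equal(as.numeric(area), c(50, 50, 0, 0))
  expect_equal(sum(area), 100)
})

test_that("a trained model segments a two-class slide accurately", {
  fit <- get_toy_fit()
  lay <- checkerboard_layout(96, 96, 2, 2, classes = 1:2)
  sl <- generate_slide(lay, seed = 9, specs = default_texture_specs(4))
  map <- segment_slide(sl$slide, fit$model, tile_size = 24, T = 8, seed = 1)
  expect_identical(dim(map$grid), c(4L, 4L))
  truth <- matrix(sl$mask[seq(12, 96, by = 24), seq(12, 96, by = 24)], 4, 4)
  expect_gte(mean(map$grid == truth), 0.9)
  expect_true(all(map$uncertainty >= 0))
  # the uncertainty grid never influences the class grid: recompute the
  # class decisions independently from the posterior means alone
  tiles <- tile_image(sl$slide, 24)
  X <- tilebayes:::stack_pixels(tiles, fit$model$config$input_size)
  mean_only <- tilebayes:::mc_proba_batch(fit$model, X, length(tiles), 8,
                                          seed = 1, uncertainty = FALSE)$mean
  grid2 <- matrix(max.col(mean_only, ties.method = "first"), 4, 4,
                  byrow = TRUE)
  expect_identical(map$grid, grid2)
})

test_that("rendering stitches class colours and blurs only near edges", {
  catalog <- class_catalog(c("a", "b"),
                          colors = rbind(c(255, 0, 0), c(0, 0, 255)))
  map <- structure(list(grid = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                        uncertainty = matrix(0, 2, 2), tile_size = 20,
                        n_classes = 2), class = "segmentation_map")
  img0 <- render_segmentation(map, catalog, blur_sigma = 0)
  expect_identical(dim(img0), c(40L, 40L, 3L))
  # exact blocks: each 20x20 block is uniform in the class colour
  expect_true(all(img0[1:20, 1:20, 1] == 255))
  expect_true(all(img0[1:20, 1:20, 3] == 0))
  expect_true(all(img0[1:20, 21:40, 3] == 255))

  sigma <- 3
  imgb <- render_segmentation(map, catalog, blur_sigma = sigma)
  d <- abs(imgb - img0)
  # the only class boundary is the vertical edge at column 20/21: pixels
  # farther than 3*sigma from it are untouched
  far <- d[, c(1:(20 - 3 * sigma), (21 + 3 * sigma):40), ]
  expect_lt(max(far), 1e-6)
  near <- d[, 19:22, ]
  expect_gt(max(near), 1)
})

test_that("segmentation outputs write to disk", {
  catalog <- class_catalog(c("a", "b"))
  map <- structure(list(grid = matrix(c(1L, 2L), 1, 2),
                        uncertainty = matrix(0.5, 1, 2), tile_size = 10,
                        n_classes = 2), class = "segmentation_map")
  map$class_area <- class_area_statistics(map)
  prefix <- file.path(withr::local_tempdir(), "s")
  files <- write_segmentation(map, catalog, prefix)
  expect_true(all(file.exists(files)))
})
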