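# Tile-based whole-slide segmentation: non-overlapping tiling, per-tile
# classification with MC-dropout uncertainty, colour stitching with optional
# Gaussian smoothing, and class surface-area statistics.

#' Split a slide into non-overlapping square tiles
#'
#' Tiles are extracted in row-major order on a `floor(H/t) x floor(W/t)`
#' grid; partial edge tiles are dropped. Tile `(r, c)` covers the half-open
#' pixel box `[(r-1)t+1, rt] x [(c-1)t+1, ct]` (1-based rows/columns).
#'
#' @param slide H x W x 3 pixel array (0..255) or H x W matrix (replicated
#'   to 3 channels).
#' @param tile_size Tile side length `t` in pixels; must not exceed either
#'   slide dimension.
#' @return List of [image_patch()] objects with ids `tile_r<r>_c<c>` and
#'   attributes `row`, `col`; the grid shape is attached as attribute
#'   `grid_dim`.
#' @export
tile_image <- function(slide, tile_size) {
  if (length(dim(slide)) == 2L) {
    slide <- array(rep(slide, 3L), dim = c(dim(slide), 3L))
  }
  d <- dim(slide)
  tile_size <- stopifnot_scalar_int(tile_size, "tile_size", min = 1)
  if (tile_size > d[1] || tile_size > d[2]) {
    stop(sprintf("tile_size %d exceeds slide dimensions %d x %d",
                 tile_size, d[1], d[2]), call. = FALSE)
  }
  R <- d[1] %/% tile_size
  C <- d[2] %/% tile_size
  tiles <- vector("list", R * C)
  k <- 0L
  for (r in seq_len(R)) {
    rows <- ((r - 1L) * tile_size + 1L):(r * tile_size)
    for (cc in seq_len(C)) {
      cols <- ((cc - 1L) * tile_size + 1L):(cc * tile_size)
      k <- k + 1L
      p <- image_patch(slide[rows, cols, , drop = FALSE],
                       id = sprintf("tile_r%d_c%d", r, cc))
      attr(p, "row") <- r
      attr(p, "col") <- cc
      tiles[[k]] <- p
    }
  }
  attr(tiles, "grid_dim") <- c(R, C)
  tiles
}

#' Segment a slide by classifying its tiles
#'
#' Splits the slide into `tile_size` tiles, bilinearly upscales each to the
#' model input size, classifies it by the argmax of the T-sample MC-dropout
#' posterior mean and records the predictive entropy H per tile. The
#' uncertainty is reported alongside but never alters the class decision.
#'
#' `model` may also be a plain function mapping an [image_patch()] to an
#' M-vector of class probabilities — an oracle hook used to validate the
#' area bookkeeping independently of any trained network (such a function
#' receives each tile with its `row`/`col` attributes).
#'
#' @param slide H x W x 3 pixel array (0..255).
#' @param model A trained `tile_classifier`, or an oracle function.
#' @param tile_size Tile side in pixels (default 50).
#' @param T Variational samples per tile (default 50; ignored for oracle
#'   functions).
#' @param seed Seed for the MC mask stream.
#' @param n_classes Number of classes (required for oracle functions;
#'   taken from the model otherwise).
#' @return An object of class `segmentation_map`: list with `grid` (R x C
#'   class-index matrix), `uncertainty` (R x C matrix of H in nats),
#'   `tile_size`, `n_classes` and `class_area` (named percentages summing
#'   to 100).
#' @export
segment_slide <- function(slide, model, tile_size = 50, T = 50, seed = 0,
                          n_classes = NULL) {
  tiles <- tile_image(slide, tile_size)
  gd <- attr(tiles, "grid_dim")
  R <- gd[1]; C <- gd[2]
  if (is.function(model)) {
    if (is.null(n_classes)) {
      stop("`n_classes` is required when `model` is an oracle function",
           call. = FALSE)
    }
    probs <- t(vapply(tiles, function(p) as.numeric(model(p)),
                      numeric(n_classes)))
    Hv <- apply(probs, 1L, shannon_entropy)
    pred <- max.col(probs, ties.method = "first")
    m <- n_classes
  } else {
    stopifnot(inherits(model, "tile_classifier"))
    m <- model$config$n_classes
    X <- stack_pixels(tiles, model$config$input_size)
    res <- mc_proba_batch(model, X, length(tiles), T, seed = seed)
    pred <- max.col(res$mean, ties.method = "first")
    Hv <- res$H
  }
  # tiles are in row-major order; R matrices fill column-major
  grid <- matrix(pred, nrow = R, ncol = C, byrow = TRUE)
  unc <- matrix(Hv, nrow = R, ncol = C, byrow = TRUE)
  map <- structure(list(grid = grid, uncertainty = unc,
                        tile_size = tile_size, n_classes = m),
                   class = "segmentation_map")
  map$class_area <- class_area_statistics(map)
  map
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d x %d tiles of %d px, %d classes\n",
              nrow(x$grid), ncol(x$grid), x$tile_size, x$n_classes))
  print(round(x$class_area, 2))
  invisible(x)
}

#' Class surface-area percentages of a segmentation
#'
#' Percentage of tiles assigned to each class; classes absent from the grid
#' report 0. Percentages always sum to 100 and are computed from the raw
#' class grid (never from a blurred rendering).
#'
#' @param map A `segmentation_map`.
#' @return Named numeric vector of length `n_classes`, in percent.
#' @export
class_area_statistics <- function(map) {
  stopifnot(inherits(map, "segmentation_map"))
  counts <- tabulate(map$grid, nbins = map$n_classes)
  out <- 100 * counts / length(map$grid)
  names(out) <- as.character(seq_len(map$n_classes))
  out
}

#' Render a segmentation as a colour image
#'
#' Paints each tile with its class colour, stitches the tiles in grid
#' order, and optionally smooths region edges with a Gaussian filter
#' (applied per colour channel). The blur is purely cosmetic: class-area
#' statistics come from the unblurred class grid.
#'
#' @param map A `segmentation_map`.
#' @param catalog A [class_catalog()] supplying one RGB colour per class.
#' @param blur_sigma Gaussian sigma in pixels; default `tile_size / 4`, use
#'   0 for an exact block image.
#' @return `(R * t) x (C * t) x 3` numeric array with values in 0..255.
#' @export
render_segmentation <- function(map, catalog,
                                blur_sigma = map$tile_size / 4) {
  stopifnot(inherits(map, "segmentation_map"),
            inherits(catalog, "class_catalog"),
            length(catalog$names) >= map$n_classes)
  t <- map$tile_size
  block <- matrix(1, t, t)
  img <- array(0, dim = c(nrow(map$grid) * t, ncol(map$grid) * t, 3))
  for (ch in 1:3) {
    colour_grid <- matrix(catalog$colors[map$grid, ch],
                          nrow = nrow(map$grid), ncol = ncol(map$grid))
    img[, , ch] <- kronecker(colour_grid, block)
  }
  # the Gaussian brush spans 2*ceiling(3*sigma)+1 pixels and must fit
  # inside the rendered image
  max_sigma <- ((min(dim(img)[1:2]) - 1) %/% 2) / 3
  blur_sigma <- min(blur_sigma, max_sigma)
  if (blur_sigma > 0) {
    blurred <- EBImage::gblur(EBImage::Image(img / 255, colormode = "Color"),
                              sigma = blur_sigma, boundary = "replicate")
    img <- clamp(EBImage::imageData(blurred) * 255, 0, 255)
  }
  img
}

#' Write segmentation outputs to files
#'
#' Writes the rendered PNG, the class grid and uncertainty grid as CSV, and
#' the class-area percentages as a JSON-ish plain-text table.
#'
#' @param map A `segmentation_map`.
#' @param catalog A [class_catalog()].
#' @param prefix Output path prefix.
#' @param blur_sigma Passed to [render_segmentation()].
#' @return Invisibly, the vector of files written.
#' @export
write_segmentation <- function(map, catalog, prefix,
                               blur_sigma = map$tile_size / 4) {
  img <- render_segmentation(map, catalog, blur_sigma)
  png_path <- paste0(prefix, "_segmentation.png")
  EBImage::writeImage(EBImage::Image(img / 255, colormode = "Color"), png_path)
  grid_path <- paste0(prefix, "_classes.csv")
  utils::write.table(map$grid, grid_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  unc_path <- paste0(prefix, "_uncertainty.csv")
  utils::write.table(map$uncertainty, unc_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  area_path <- paste0(prefix, "_class_area.csv")
  area <- data.frame(class = catalog$names[seq_len(map$n_classes)],
                     area_pct = as.numeric(map$class_area))
  utils::write.csv(area, area_path, row.names = FALSE)
  invisible(c(png_path, grid_path, unc_path, area_path))
}
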