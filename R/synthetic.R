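# Procedural generator of textured tiles and composite slides with known
# region masks. The textures are oriented sinusoidal gratings with
# class-specific two-colour palettes, plus Gaussian blob perturbations and
# additive pixel noise: cheap to generate, learnable by small CNNs, and with
# a continuous "confusability" dial that blends the generative parameters of
# a designated class pair to emulate genuinely ambiguous tissue classes.

#' Texture specification for one synthetic class
#'
#' @param class_index 1-based class index the texture belongs to.
#' @param base_frequency Grating frequency in cycles per tile (> 0).
#' @param orientation Grating orientation in degrees.
#' @param palette 2 x 3 matrix of RGB triples (0..255): the two colours the
#'   grating interpolates between.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units (>= 0).
#' @param confusability Blend weight in `[0, 1]` toward `partner`: each
#'   generated patch draws a mixing weight uniformly from
#'   `[0, confusability]` and interpolates all generative parameters toward
#'   the partner class by that amount. At 1 the patch distribution is
#'   identical to the partner's (both classes draw from the full segment
#'   between the two parameter sets); at 0 the class is pure.
#' @param partner Optional `texture_spec` giving the unblended parameters of
#'   the confusable partner class.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(class_index, base_frequency, orientation, palette,
                         noise_sd = 0, confusability = 0, partner = NULL) {
  stopifnot(base_frequency > 0, noise_sd >= 0,
            confusability >= 0, confusability <= 1)
  palette <- as.matrix(palette)
  stopifnot(nrow(palette) == 2L, ncol(palette) == 3L)
  if (confusability > 0 && is.null(partner)) {
    stop("a `partner` spec is required when confusability > 0", call. = FALSE)
  }
  structure(list(class_index = as.integer(class_index),
                 base_frequency = base_frequency,
                 orientation = orientation,
                 palette = palette,
                 noise_sd = noise_sd,
                 confusability = confusability,
                 partner = partner),
            class = "texture_spec")
}

#' Default texture specifications for M synthetic classes
#'
#' Builds M visually distinct grating textures (spread orientations,
#' frequencies and hue-separated palettes). When `confusable_pair` is given,
#' both members of the pair receive the same `confusability` toward each
#' other, emulating a pair of tissue classes the classifier genuinely
#' confuses.
#'
#' @param M Number of classes (>= 2).
#' @param confusable_pair Optional length-2 vector of class indices.
#' @param confusability Blend weight in `[0, 1]` applied to the pair.
#' @param noise_sd Additive pixel noise SD shared by all classes.
#' @return List of M [texture_spec()] objects.
#' @export
default_texture_specs <- function(M, confusable_pair = NULL,
                                  confusability = 0.5, noise_sd = 12) {
  stopifnot(M >= 2)
  hues <- seq(0, 360, length.out = M + 1L)[seq_len(M)]
  base <- lapply(seq_len(M), function(ci) {
    pal <- rbind(t(grDevices::col2rgb(grDevices::hcl(hues[ci], 90, 35))),
                 t(grDevices::col2rgb(grDevices::hcl((hues[ci] + 60) %% 360,
                                                     70, 85))))
    texture_spec(class_index = ci,
                 base_frequency = 2 + (ci - 1L) %% 4 * 1.5,
                 orientation = (ci - 1L) * 180 / M,
                 palette = pal,
                 noise_sd = noise_sd)
  })
  if (!is.null(confusable_pair)) {
    stopifnot(length(confusable_pair) == 2L,
              all(confusable_pair %in% seq_len(M)),
              confusable_pair[1] != confusable_pair[2])
    a <- confusable_pair[1]; b <- confusable_pair[2]
    pa <- base[[a]]; pb <- base[[b]]
    base[[a]]$confusability <- confusability
    base[[a]]$partner <- pb
    base[[b]]$confusability <- confusability
    base[[b]]$partner <- pa
  }
  base
}

# Interpolate the generative parameters of `spec` toward its partner by
# weight `lambda` in [0, 1].
blend_spec_params <- function(spec, lambda) {
  if (lambda <= 0 || is.null(spec$partner)) {
    return(spec[c("base_frequency", "orientation", "palette", "noise_sd")])
  }
  p <- spec$partner
  list(base_frequency = (1 - lambda) * spec$base_frequency + lambda * p$base_frequency,
       orientation = (1 - lambda) * spec$orientation + lambda * p$orientation,
       palette = (1 - lambda) * spec$palette + lambda * p$palette,
       noise_sd = (1 - lambda) * spec$noise_sd + lambda * p$noise_sd)
}

# Deterministic texture field given already-drawn nuisance parameters.
# Returns an h x w x 3 numeric array in [0, 255] before additive noise.
render_grating <- function(pars, h, w, phase, blobs) {
  ys <- (seq_len(h) - 0.5) / max(h, w)
  xs <- (seq_len(w) - 0.5) / max(h, w)
  X <- matrix(xs, nrow = h, ncol = w, byrow = TRUE)
  Y <- matrix(ys, nrow = h, ncol = w)
  th <- pars$orientation * pi / 180
  u <- cos(th) * X + sin(th) * Y
  s <- (sin(2 * pi * pars$base_frequency * u + phase) + 1) / 2
  if (!is.null(blobs) && nrow(blobs) > 0) {
    for (i in seq_len(nrow(blobs))) {
      d2 <- (X - blobs$cx[i])^2 + (Y - blobs$cy[i])^2
      s <- s + blobs$amp[i] * exp(-d2 / (2 * blobs$width[i]^2))
    }
  }
  s <- clamp(s, 0, 1)
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    out[, , ch] <- pars$palette[1, ch] * (1 - s) + pars$palette[2, ch] * s
  }
  out
}

#' Generate one synthetic textured tile
#'
#' Deterministic for a fixed `(spec, size, rng_seed)` triple: the seed fixes
#' the confusability mixing weight, the grating phase, the blob layout and
#' the pixel noise. With `noise_sd = 0` the patch is the pure deterministic
#' texture (no additive noise is drawn).
#'
#' @param spec A [texture_spec()].
#' @param size Tile side length in pixels (>= 8); square tiles.
#' @param rng_seed Integer seed for this patch.
#' @param id Optional patch id (default encodes class and seed).
#' @return An [image_patch()] labelled with `spec$class_index`.
#' @export
generate_patch <- function(spec, size = 32, rng_seed = 1,
                           id = sprintf("class%02d/seed%d",
                                        spec$class_index, rng_seed)) {
  stopifnot(inherits(spec, "texture_spec"), size >= 8)
  with_seed(rng_seed, {
    lambda <- if (spec$confusability > 0) runif(1, 0, spec$confusability) else 0
    pars <- blend_spec_params(spec, lambda)
    phase <- runif(1, 0, 2 * pi)
    nb <- max(3L, round(size^2 / (64 * 64) * 3))
    blobs <- data.frame(cx = runif(nb, 0, 1), cy = runif(nb, 0, 1),
                        width = runif(nb, 0.08, 0.2),
                        amp = runif(nb, -0.4, 0.4))
    px <- render_grating(pars, size, size, phase, blobs)
    if (pars$noise_sd > 0) {
      px <- px + array(stats::rnorm(length(px), sd = pars$noise_sd), dim = dim(px))
    }
    image_patch(round(clamp(px, 0, 255)), id = id, label = spec$class_index)
  })
}

#' Generate a balanced synthetic tile dataset
#'
#' Emits exactly `n_per_class` tiles for each of `M` classes using
#' [default_texture_specs()]. One master seed spawns an independent
#' substream per patch (the full seed table is drawn up-front), so any
#' individual patch is reproducible regardless of generation order.
#'
#' @param M Number of classes (>= 2).
#' @param n_per_class Tiles per class (>= 1).
#' @param size Tile side length in pixels.
#' @param confusable_pair Optional class index pair passed to
#'   [default_texture_specs()].
#' @param confusability Blend weight for the pair.
#' @param noise_sd Additive pixel noise SD.
#' @param seed Integer master seed.
#' @param catalog Optional [class_catalog()]; defaults to
#'   [colorectal_catalog()] when `M = 8`, generic names otherwise.
#' @param id_prefix Prefix prepended to every patch id (e.g. `"test/"`), so
#'   independently generated datasets have disjoint id sets.
#' @return A balanced [patch_dataset()] with `M * n_per_class` patches and
#'   ids of the form `<prefix><class>/<index>`.
#' @export
generate_dataset <- function(M, n_per_class, size = 32, confusable_pair = NULL,
                             confusability = 0.5, noise_sd = 12, seed = 1,
                             catalog = NULL, id_prefix = "") {
  stopifnot(M >= 2, n_per_class >= 1)
  if (is.null(catalog)) {
    catalog <- if (M == 8L) colorectal_catalog() else
      class_catalog(sprintf("class%02d", seq_len(M)))
  }
  stopifnot(length(catalog$names) == M)
  specs <- default_texture_specs(M, confusable_pair, confusability, noise_sd)
  seeds <- with_seed(seed, matrix(sample.int(2147483644L, M * n_per_class),
                                  nrow = n_per_class, ncol = M))
  patches <- vector("list", M * n_per_class)
  k <- 0L
  for (ci in seq_len(M)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      patches[[k]] <- generate_patch(
        specs[[ci]], size = size, rng_seed = seeds[i, ci],
        id = sprintf("%s%s/%05d", id_prefix, catalog$names[ci], i))
    }
  }
  patch_dataset(patches, catalog)
}

#' Rectangular slide layout
#'
#' A canvas size plus a list of axis-aligned rectangular regions, each
#' carrying a class index. Regions must tile the canvas exactly: no overlap,
#' no gaps.
#'
#' @param width,height Canvas size in pixels.
#' @param regions Data frame with columns `x`, `y` (1-based top-left corner,
#'   `x` = column, `y` = row), `w`, `h` (extent in pixels) and `class`
#'   (1-based class index).
#' @return An object of class `slide_layout`.
#' @export
slide_layout <- function(width, height, regions) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("x", "y", "w", "h", "class") %in% names(regions)))
  if (any(regions$x < 1 | regions$y < 1 |
          regions$x + regions$w - 1 > width |
          regions$y + regions$h - 1 > height)) {
    stop("a region extends beyond the canvas", call. = FALSE)
  }
  if (sum(as.numeric(regions$w) * regions$h) != as.numeric(width) * height) {
    stop("regions do not tile the canvas exactly (area mismatch)", call. = FALSE)
  }
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (regions$x[i] < regions$x[j] + regions$w[j] &&
          regions$x[j] < regions$x[i] + regions$w[i] &&
          regions$y[i] < regions$y[j] + regions$h[j] &&
          regions$y[j] < regions$y[i] + regions$h[i]) {
        stop(sprintf("regions %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions), class = "slide_layout")
}

#' Checkerboard slide layout
#'
#' Convenience constructor: an `nr x nc` grid of equal rectangles with
#' classes assigned in checkerboard order from `classes`.
#'
#' @param width,height Canvas size in pixels (must be divisible by `nc`,
#'   `nr`).
#' @param nr,nc Grid dimensions.
#' @param classes Integer vector of class indices cycled over the grid in
#'   checkerboard fashion.
#' @return A [slide_layout()].
#' @export
checkerboard_layout <- function(width, height, nr = 2, nc = 2, classes = 1:2) {
  stopifnot(width %% nc == 0, height %% nr == 0)
  cw <- width %/% nc; ch <- height %/% nr
  regions <- do.call(rbind, lapply(seq_len(nr), function(r) {
    do.call(rbind, lapply(seq_len(nc), function(cc) {
      data.frame(x = (cc - 1L) * cw + 1L, y = (r - 1L) * ch + 1L,
                 w = cw, h = ch,
                 class = classes[(r + cc - 2L) %% length(classes) + 1L])
    }))
  }))
  slide_layout(width, height, regions)
}

#' Generate a composite synthetic slide with a known label mask
#'
#' Fills each layout region with its class texture and returns both the
#' rendered slide and the per-pixel ground-truth class mask.
#'
#' @param layout A [slide_layout()].
#' @param seed Integer master seed (each region gets a derived substream).
#' @param specs Optional list of [texture_spec()] (defaults to
#'   [default_texture_specs()] over the classes present).
#' @param noise_sd Additive pixel noise SD used when `specs` is `NULL`.
#' @return A list with `slide` (H x W x 3 integer array, 0..255) and `mask`
#'   (H x W integer matrix of class indices).
#' @export
generate_slide <- function(layout, seed = 1, specs = NULL, noise_sd = 12) {
  stopifnot(inherits(layout, "slide_layout"))
  M <- max(layout$regions$class)
  if (is.null(specs)) specs <- default_texture_specs(max(M, 2), noise_sd = noise_sd)
  slide <- array(0L, dim = c(layout$height, layout$width, 3))
  mask <- matrix(0L, nrow = layout$height, ncol = layout$width)
  for (i in seq_len(nrow(layout$regions))) {
    r <- layout$regions[i, ]
    rows <- r$y:(r$y + r$h - 1L)
    cols <- r$x:(r$x + r$w - 1L)
    px <- with_seed(derive_seed(seed, i), {
      spec <- specs[[r$class]]
      pars <- blend_spec_params(spec, 0)
      phase <- runif(1, 0, 2 * pi)
      nb <- max(3L, round(as.numeric(r$w) * r$h / (64 * 64) * 3))
      blobs <- data.frame(cx = runif(nb), cy = runif(nb),
                          width = runif(nb, 0.08, 0.2),
                          amp = runif(nb, -0.4, 0.4))
      out <- render_grating(pars, r$h, r$w, phase, blobs)
      if (pars$noise_sd > 0) {
        out <- out + array(stats::rnorm(length(out), sd = pars$noise_sd),
                           dim = dim(out))
      }
      out
    })
    slide[rows, cols, ] <- as.integer(round(clamp(px, 0, 255)))
    mask[rows, cols] <- r$class
  }
  list(slide = slide, mask = mask)
}
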