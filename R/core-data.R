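# Core domain types: tiles, class catalogs, tile datasets and stratified
# splits, plus directory-tree readers/writers for the class-per-directory
# layout common to annotated histology tile collections.

#' Create a single image tile
#'
#' An `image_patch` is one small RGB tile: an H x W x 3 array of 8-bit
#' channel intensities, a stable identifier, and an optional class label.
#' Labels are 1-based class indices into a [class_catalog()].
#'
#' @param pixels Numeric or integer H x W x 3 array with values in 0..255.
#' @param id Character scalar, unique within a dataset.
#' @param label Optional integer class label in `1..M`, or `NA` if unknown.
#' @return An object of class `image_patch`.
#' @examples
#' p <- image_patch(array(128L, dim = c(8, 8, 3)), id = "tile-1", label = 1L)
#' dim(p$pixels)
#' @export
image_patch <- function(pixels, id, label = NA_integer_) {
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    stop("`pixels` must be an H x W x 3 array with H, W >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("`id` must be a non-empty character scalar", call. = FALSE)
  }
  structure(list(id = id, pixels = pixels, label = as.integer(label)),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_patch> id=%s  %dx%d px  label=%s\n",
              x$id, d[1], d[2],
              if (is.na(x$label)) "?" else x$label))
  invisible(x)
}

#' Create a class catalog
#'
#' Ordered class names plus one display colour per class (used when
#' rendering segmentations). Names must be unique.
#'
#' @param names Character vector of M unique class names.
#' @param colors Optional M x 3 matrix of RGB triples in 0..255; a default
#'   qualitative palette is generated when omitted.
#' @return An object of class `class_catalog`.
#' @export
class_catalog <- function(names, colors = NULL) {
  if (anyDuplicated(names)) stop("class names must be unique", call. = FALSE)
  m <- length(names)
  if (m < 1L) stop("at least one class is required", call. = FALSE)
  if (is.null(colors)) {
    hex <- grDevices::hcl(h = seq(15, 375, length.out = m + 1L)[seq_len(m)],
                          c = 100, l = 60)
    colors <- t(grDevices::col2rgb(hex))
  }
  colors <- as.matrix(colors)
  if (nrow(colors) != m || ncol(colors) != 3L) {
    stop("`colors` must be an M x 3 RGB matrix", call. = FALSE)
  }
  storage.mode(colors) <- "integer"
  dimnames(colors) <- list(names, c("r", "g", "b"))
  structure(list(names = as.character(names), colors = colors),
            class = "class_catalog")
}

#' The eight colorectal tissue classes
#'
#' Convenience catalog with the eight tissue class names commonly used for
#' colorectal histology tile collections (tumour epithelium, simple stroma,
#' complex stroma, immune cells, debris, normal mucosa, adipose,
#' background).
#'
#' @return A [class_catalog()] with 8 classes.
#' @export
colorectal_catalog <- function() {
  class_catalog(c("Tumour", "Stroma", "Complex", "Lympho",
                  "Debris", "Mucosa", "Adipose", "Empty"))
}

#' Create a tile dataset
#'
#' A `patch_dataset` bundles a sequence of [image_patch()] objects with the
#' [class_catalog()] their labels refer to. Iteration order is the order of
#' `patches` and is deterministic given identical construction.
#'
#' @param patches List of [image_patch()] objects.
#' @param catalog A [class_catalog()].
#' @return An object of class `patch_dataset`.
#' @export
patch_dataset <- function(patches, catalog) {
  stopifnot(inherits(catalog, "class_catalog"))
  m <- length(catalog$names)
  ids <- vapply(patches, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("patch ids must be unique", call. = FALSE)
  labs <- vapply(patches, function(p) p$label, integer(1))
  bad <- !is.na(labs) & (labs < 1L | labs > m)
  if (any(bad)) {
    stop(sprintf("labels outside 1..%d for ids: %s", m,
                 paste(ids[bad][seq_len(min(3, sum(bad)))], collapse = ", ")),
         call. = FALSE)
  }
  structure(list(patches = patches, catalog = catalog), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches, %d classes\n",
              n_patches(x), length(x$catalog$names)))
  cc <- class_counts(x)
  if (n_patches(x) > 0) print(cc)
  invisible(x)
}

#' Number of patches in a dataset
#' @param dataset A [patch_dataset()].
#' @return Integer count.
#' @export
n_patches <- function(dataset) length(dataset$patches)

#' Patch ids of a dataset, in iteration order
#' @param dataset A [patch_dataset()].
#' @return Character vector.
#' @export
patch_ids <- function(dataset) {
  vapply(dataset$patches, function(p) p$id, character(1))
}

#' Patch labels of a dataset, in iteration order
#' @param dataset A [patch_dataset()].
#' @return Integer vector (may contain `NA` for unlabelled patches).
#' @export
patch_labels <- function(dataset) {
  vapply(dataset$patches, function(p) p$label, integer(1))
}

#' Per-class patch counts
#' @param dataset A [patch_dataset()].
#' @return Named integer vector, one entry per catalog class.
#' @export
class_counts <- function(dataset) {
  labs <- patch_labels(dataset)
  m <- length(dataset$catalog$names)
  out <- tabulate(labs[!is.na(labs)], nbins = m)
  names(out) <- dataset$catalog$names
  out
}

#' Subset a dataset by patch ids
#'
#' @param dataset A [patch_dataset()].
#' @param ids Character vector of ids to keep; order of `ids` is preserved.
#' @return A [patch_dataset()] with the selected patches.
#' @export
dataset_subset <- function(dataset, ids) {
  all_ids <- patch_ids(dataset)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) {
    stop(sprintf("unknown ids: %s",
                 paste(ids[is.na(idx)][1:min(3, sum(is.na(idx)))],
                       collapse = ", ")), call. = FALSE)
  }
  patch_dataset(dataset$patches[idx], dataset$catalog)
}

supported_image_ext <- c("png", "tif", "tiff", "jpg", "jpeg")

read_patch_file <- function(path, id, label) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop(sprintf(
                    "cannot read image file '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3] # drop alpha
  image_patch(round(px * 255), id = id, label = label)
}

#' Load a class-per-directory tile dataset
#'
#' Reads a directory tree with one subdirectory per catalog class, each
#' holding PNG/TIFF/JPEG tile images. Every image becomes a labelled
#' [image_patch()]; ids are relative paths (`class/file`), and patches are
#' ordered lexicographically by id so loading is deterministic across
#' platforms.
#'
#' @param root_path Directory containing one subdirectory per class name.
#' @param catalog A [class_catalog()] naming the expected subdirectories.
#' @return A [patch_dataset()].
#' @export
load_tile_dataset <- function(root_path, catalog) {
  stopifnot(inherits(catalog, "class_catalog"))
  patches <- list()
  for (ci in seq_along(catalog$names)) {
    cls <- catalog$names[ci]
    dir <- file.path(root_path, cls)
    if (!dir.exists(dir)) {
      stop(sprintf("missing class directory '%s' under '%s'", cls, root_path),
           call. = FALSE)
    }
    files <- list.files(dir, pattern = paste0(
      "\\.(", paste(supported_image_ext, collapse = "|"), ")$"),
      ignore.case = TRUE)
    files <- sort(files, method = "radix")
    for (f in files) {
      id <- paste(cls, f, sep = "/")
      patches[[length(patches) + 1L]] <-
        read_patch_file(file.path(dir, f), id = id, label = ci)
    }
  }
  if (length(patches) > 0) {
    ord <- order(vapply(patches, function(p) p$id, character(1)),
                 method = "radix")
    patches <- patches[ord]
  }
  patch_dataset(patches, catalog)
}

#' Write a tile dataset as a class-per-directory tree
#'
#' Inverse of [load_tile_dataset()]: writes each patch as a PNG file under
#' `root_path/<class>/`. Unlabelled patches go under `unlabelled/`. Ids of
#' the form `class/file` keep their file name; other ids are sanitised.
#'
#' @param dataset A [patch_dataset()].
#' @param root_path Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_tile_dataset <- function(dataset, root_path) {
  written <- character(0)
  for (p in dataset$patches) {
    cls <- if (is.na(p$label)) "unlabelled" else dataset$catalog$names[p$label]
    dir <- file.path(root_path, cls)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    base <- basename(p$id)
    if (!grepl("\\.(png|tif|tiff|jpg|jpeg)$", base, ignore.case = TRUE)) {
      base <- paste0(gsub("[^A-Za-z0-9._-]", "_", base), ".png")
    } else {
      base <- sub("\\.(tif|tiff|jpg|jpeg)$", ".png", base, ignore.case = TRUE)
    }
    path <- file.path(dir, base)
    img <- EBImage::Image(p$pixels / 255, colormode = "Color")
    EBImage::writeImage(img, path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Seeded stratified holdout splits
#'
#' Produces `k` independent train/test splits of a labelled dataset. Each
#' split draws `ceiling(n_c / k)` test patches per class `c` without
#' replacement under a seed derived from `seed` and the split index; the
#' training set is the complement. The splits are seeded repeats (each is a
#' fresh stratified draw), not a partition of the dataset: with 8 balanced
#' classes of 625 tiles and `k = 10` every split has a 504-tile test set
#' (63 per class) and a 4496-tile training set (562 per class).
#'
#' @param dataset A fully labelled [patch_dataset()].
#' @param k Integer number of splits, `>= 2`; also sets the per-class test
#'   fraction `1/k`.
#' @param seed Integer master seed.
#' @return A list of `k` objects of class `split_spec`, each with
#'   `train_ids`, `test_ids`, `seed` and `fold`.
#' @export
stratified_holdout <- function(dataset, k, seed) {
  k <- stopifnot_scalar_int(k, "k", min = 2)
  labs <- patch_labels(dataset)
  if (anyNA(labs)) stop("all patches must be labelled", call. = FALSE)
  ids <- patch_ids(dataset)
  m <- length(dataset$catalog$names)
  by_class <- split(ids, factor(labs, levels = seq_len(m)))
  sizes <- lengths(by_class)
  present <- sizes > 0
  if (any(sizes[present] < k)) {
    small <- dataset$catalog$names[present][sizes[present] < k]
    stop(sprintf("class '%s' has fewer than k = %d members", small[1], k),
         call. = FALSE)
  }
  lapply(seq_len(k), function(fold) {
    test_ids <- with_seed(derive_seed(seed, fold), {
      unlist(lapply(by_class[present], function(cls_ids) {
        cls_ids <- sort(cls_ids, method = "radix")
        sample(cls_ids, ceiling(length(cls_ids) / k))
      }), use.names = FALSE)
    })
    structure(list(train_ids = setdiff(ids, test_ids),
                   test_ids = test_ids,
                   seed = as.integer(seed), fold = fold),
              class = "split_spec")
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> fold %d: %d train / %d test (seed %d)\n",
              x$fold, length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Write a split as a two-column plain-text table
#'
#' @param split A `split_spec` from [stratified_holdout()].
#' @param path Output TSV path with columns `id` and `role`
#'   (train/test).
#' @return Invisibly, `path`.
#' @export
write_split <- function(split, path) {
  df <- rbind(data.frame(id = split$train_ids, role = "train"),
              data.frame(id = split$test_ids, role = "test"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a split written by [write_split()]
#'
#' @param path TSV path.
#' @return A `split_spec` (with `seed`/`fold` unknown).
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(train_ids = df$id[df$role == "train"],
                 test_ids = df$id[df$role == "test"],
                 seed = NA_integer_, fold = NA_integer_),
            class = "split_spec")
}
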