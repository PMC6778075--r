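# Identification of mislabelled training tiles: confident (low-H)
# misclassifications below a per-class entropy percentile, plus the
# planted-noise evaluation protocol.

#' Plant random label noise in a dataset
#'
#' Relabels `round(p_m/100 * N)` uniformly sampled patches, each to a class
#' drawn uniformly from the other `M - 1` classes (never its own), and
#' returns the corrupted dataset together with the planted id set as ground
#' truth.
#'
#' @param dataset A fully labelled [patch_dataset()] with at least 2
#'   classes.
#' @param p_m Percentage of patches to corrupt, in `[0, 100]`.
#' @param seed Integer seed.
#' @return A list with `dataset` (corrupted) and `planted` (character ids).
#' @export
plant_label_noise <- function(dataset, p_m, seed = 1) {
  if (length(p_m) != 1L || is.na(p_m) || p_m < 0 || p_m > 100) {
    stop("`p_m` must be a percentage in [0, 100]", call. = FALSE)
  }
  m <- length(dataset$catalog$names)
  if (m < 2L) stop("at least two classes are required", call. = FALSE)
  n <- n_patches(dataset)
  n_flip <- round(p_m / 100 * n)
  if (n_flip == 0L) return(list(dataset = dataset, planted = character(0)))
  ids <- patch_ids(dataset)
  flip <- with_seed(derive_seed(seed, 1L), sample(seq_len(n), n_flip))
  new_labels <- with_seed(derive_seed(seed, 2L), {
    vapply(flip, function(i) {
      old <- dataset$patches[[i]]$label
      sample(setdiff(seq_len(m), old), 1L)
    }, integer(1))
  })
  patches <- dataset$patches
  for (j in seq_along(flip)) {
    patches[[flip[j]]]$label <- new_labels[j]
  }
  list(dataset = patch_dataset(patches, dataset$catalog),
       planted = ids[flip])
}

#' Per-class entropy thresholds
#'
#' For each class `c`, the threshold is the `p_m`-th percentile of the
#' empirical distribution of `H` among records whose assigned label is `c`
#' (linear interpolation between closest ranks, inclusive endpoints — the
#' type-7 empirical quantile). Classes with no records are omitted with a
#' warning.
#'
#' @param records Data frame from [score_dataset()] carrying `true_label`
#'   (the assigned, possibly wrong, label) and `H`.
#' @param p_m Percentile in `[0, 100]`: the expected mislabelled fraction.
#' @return Named numeric vector of thresholds, one per class present.
#' @export
per_class_thresholds <- function(records, p_m) {
  stopifnot(p_m >= 0, p_m <= 100)
  if (anyNA(records$true_label)) {
    stop("records must carry assigned labels", call. = FALSE)
  }
  classes <- sort(unique(records$true_label))
  out <- vapply(classes, function(cl) {
    stats::quantile(records$H[records$true_label == cl], probs = p_m / 100,
                    type = 7, names = FALSE)
  }, numeric(1))
  names(out) <- as.character(classes)
  out
}

#' Identify candidate mislabelled tiles
#'
#' Per class `c`, candidates are the records misclassified by the model
#' (predicted class differs from the assigned label `c`) whose entropy `H`
#' lies strictly below the class threshold from [per_class_thresholds()].
#' The report is the union of candidates across classes.
#'
#' @inheritParams per_class_thresholds
#' @return An object of class `mislabel_report`: list with `thresholds`,
#'   `candidates` (character ids), `per_class` (ids by class) and `p_m`.
#' @export
identify_mislabelled <- function(records, p_m) {
  thr <- per_class_thresholds(records, p_m)
  per_class <- lapply(names(thr), function(cl) {
    sel <- records$true_label == as.integer(cl) &
      records$predicted != records$true_label &
      records$H < thr[[cl]]
    records$id[sel]
  })
  names(per_class) <- names(thr)
  structure(list(thresholds = thr,
                 candidates = unique(unlist(per_class, use.names = FALSE)),
                 per_class = per_class, p_m = p_m),
            class = "mislabel_report")
}

#' @export
print.mislabel_report <- function(x, ...) {
  cat(sprintf("<mislabel_report> p_m=%g%%: %d candidate(s) across %d class(es)\n",
              x$p_m, length(x$candidates), length(x$thresholds)))
  invisible(x)
}

#' Evaluate mislabel identification against planted ground truth
#'
#' With `P` the candidate set: reports `sensitivity = |planted ∩ P| / |P|`
#' and `specificity = |clean ∩ non-candidates| / |non-candidates|`
#' (the planted-noise bookkeeping convention in which the positives are the
#' identified candidates), plus the standard `recall =
#' |planted ∩ P| / |planted|` for transparency. When `P` is empty,
#' sensitivity is undefined and reported as `NA` with a warning.
#'
#' @param report A `mislabel_report` (or character vector of candidate ids).
#' @param planted Character ids of the artificially mislabelled patches.
#' @param all_ids Character ids of every patch that was scored.
#' @return Named list with `sensitivity`, `specificity`, `recall`,
#'   `n_candidates`, `n_planted`.
#' @export
evaluate_identification <- function(report, planted, all_ids) {
  candidates <- if (inherits(report, "mislabel_report")) report$candidates
                else as.character(report)
  stopifnot(all(planted %in% all_ids), all(candidates %in% all_ids))
  tp <- length(intersect(planted, candidates))
  non_cand <- setdiff(all_ids, candidates)
  clean <- setdiff(all_ids, planted)
  sens <- if (length(candidates) == 0L) {
    warning(sprintf(
      "no candidates identified (|planted| = %d): sensitivity undefined",
      length(planted)))
    NA_real_
  } else tp / length(candidates)
  list(sensitivity = sens,
       specificity = if (length(non_cand) == 0L) NA_real_ else
         length(intersect(clean, non_cand)) / length(non_cand),
       recall = if (length(planted) == 0L) NA_real_ else tp / length(planted),
       n_candidates = length(candidates),
       n_planted = length(planted))
}
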