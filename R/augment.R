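#' The seven-way class scheme
#'
#' @return Character vector of the seven class labels.
#' @export
plankton_classes <- function()
  c("chaetognatha", "copepoda", "medusae", "euphausiids",
    "fish_larvae", "limacina", "other")

#' Labeled sample container
#'
#' @param crop Integer intensity matrix.
#' @param label Class label.
#' @param mask Optional logical target mask of the crop's shape.
#' @param roi_id Base ROI identifier (augmented variants keep their
#'   base's id so split disjointness can be audited).
#' @param tag Augmentation tag (`""` for originals).
#' @param i_max Maximum representable intensity.
#' @return An object of class `labeled_sample`.
#' @export
labeled_sample <- function(crop, label, mask = NULL, roi_id = "s0",
                           tag = "", i_max = 255L) {
  if (!is.matrix(crop)) stop("crop must be a matrix")
  if (!is.null(mask) && !identical(dim(mask), dim(crop)))
    stop("mask dimensions differ from crop")
  structure(list(crop = crop, mask = mask, label = as.character(label),
                 roi_id = as.character(roi_id), tag = as.character(tag),
                 i_max = as.integer(i_max)),
            class = "labeled_sample")
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180_cw <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
mirror_ud <- function(m) m[nrow(m):1, , drop = FALSE]
mirror_lr <- function(m) m[, ncol(m):1, drop = FALSE]

# Linear rescale of the crop to the full [0, i_max] dynamic range.
contrast_widen <- function(m, i_max = 255L) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m)
  out <- round_half_up((m - lo) / (hi - lo) * i_max)
  storage.mode(out) <- "integer"
  out
}

augmentation_ops <- c("ROT90_CW", "ROT180_CW", "MIRROR_UD",
                      "MIRROR_LR", "CONTRAST_WIDEN")

apply_op <- function(sample, op) {
  f <- switch(op,
              ROT90_CW = rot90_cw, ROT180_CW = rot180_cw,
              MIRROR_UD = mirror_ud, MIRROR_LR = mirror_lr,
              CONTRAST_WIDEN = function(m) contrast_widen(m, sample$i_max),
              stop("unknown augmentation op: ", op))
  out <- sample
  out$crop <- f(sample$crop)
  if (!is.null(sample$mask))
    out$mask <- if (op == "CONTRAST_WIDEN") sample$mask else
      (f(sample$mask * 1L) > 0L)
  out$tag <- if (nzchar(sample$tag)) paste0(sample$tag, "+", op) else op
  out
}

#' Rarity augmentation recipe
#'
#' @param name Recipe name.
#' @param ops Ordered subset of `ROT90_CW`, `ROT180_CW`, `MIRROR_UD`,
#'   `MIRROR_LR`, `CONTRAST_WIDEN`, each at most once.
#' @param applies_to Class labels the recipe may be applied to.
#' @return An `augmentation_recipe` list.
#' @export
augmentation_recipe <- function(name, ops, applies_to) {
  if (!length(ops)) stop("recipe needs at least one op")
  if (anyDuplicated(ops)) stop("each op may appear at most once")
  bad <- setdiff(ops, augmentation_ops)
  if (length(bad)) stop("unknown ops: ", paste(bad, collapse = ", "))
  structure(list(name = name, ops = ops, applies_to = applies_to),
            class = "augmentation_recipe")
}

#' Default class-rarity recipes
#'
#' Euphausiids (threefold expansion): rotate 90 and 180 degrees
#' clockwise and mirror up-down. Chaetognatha and medusae (fourfold):
#' additionally mirror left-right. Fish larvae (fivefold):
#' additionally widen the grayscale dynamic range.
#'
#' @return Named list of [augmentation_recipe()]s keyed by class.
#' @export
default_recipes <- function() {
  three <- c("ROT90_CW", "ROT180_CW", "MIRROR_UD")
  four <- c(three, "MIRROR_LR")
  five <- c(four, "CONTRAST_WIDEN")
  list(
    euphausiids = augmentation_recipe("threefold", three, "euphausiids"),
    chaetognatha = augmentation_recipe("fourfold", four, "chaetognatha"),
    medusae = augmentation_recipe("fourfold", four, "medusae"),
    fish_larvae = augmentation_recipe("fivefold", five, "fish_larvae"))
}

#' Apply a rarity recipe to one sample
#'
#' Returns one new sample per recipe op (the original is not
#' included), each tagged with its op and keeping the base `roi_id`
#' and label.
#'
#' @param sample A [labeled_sample()].
#' @param recipe An [augmentation_recipe()] whose `applies_to`
#'   includes the sample's class.
#' @return List of `length(recipe$ops)` new samples.
#' @export
apply_rarity_recipe <- function(sample, recipe) {
  stopifnot(inherits(sample, "labeled_sample"),
            inherits(recipe, "augmentation_recipe"))
  if (!sample$label %in% recipe$applies_to)
    stop("recipe '", recipe$name, "' does not apply to class ",
         sample$label)
  lapply(recipe$ops, function(op) apply_op(sample, op))
}

#' Contrast level set
#'
#' The boundary-parameter values used to mimic different imaging
#' conditions; each must lie in `[3, 4]`.
#'
#' @param deltas Ordered numeric vector
#'   (default `c(3.1, 3.3, 3.5, 3.7, 3.9)`).
#' @return A `contrast_level_set`.
#' @export
contrast_levels <- function(deltas = c(3.1, 3.3, 3.5, 3.7, 3.9)) {
  if (any(deltas < 3 | deltas > 4))
    stop("all contrast levels must lie in [3, 4]")
  structure(list(deltas = deltas), class = "contrast_level_set")
}

#' Expand samples over contrast levels
#'
#' Each sample yields one variant per level: the background
#' suppression transform ([suppress_background()]) evaluated at that
#' boundary parameter. Samples must carry a mask; with
#' `fallback_stretch = TRUE`, mask-free samples instead get a linear
#' contrast stretch toward the range implied by the level. The output
#' has exactly `length(samples) * length(levels$deltas)` samples;
#' level 3 reproduces the input up to rounding.
#'
#' @param samples List of [labeled_sample()]s.
#' @param levels A [contrast_levels()] set.
#' @param fallback_stretch Allow mask-free samples (default `FALSE`).
#' @return List of augmented samples tagged `delta<value>`.
#' @export
apply_contrast_levels <- function(samples, levels = contrast_levels(),
                                  fallback_stretch = FALSE) {
  out <- vector("list", length(samples) * length(levels$deltas))
  k <- 0L
  for (s in samples) {
    if (is.null(s$mask) && !fallback_stretch)
      stop("sample '", s$roi_id, "' has no mask; ",
           "contrast-level expansion needs one")
    for (d in levels$deltas) {
      v <- s
      v$crop <- if (is.null(s$mask))
        contrast_widen(s$crop, s$i_max)
      else
        suppress_background(s$crop, suppression_params(d),
                            mask = s$mask, i_max = s$i_max)
      v$tag <- if (nzchar(s$tag)) sprintf("%s+delta%.1f", s$tag, d)
               else sprintf("delta%.1f", d)
      k <- k + 1L
      out[[k]] <- v
    }
  }
  out
}

sample_manifest <- function(samples, split) {
  if (!length(samples)) return(manifest())
  df <- data.frame(
    path = vapply(samples, function(s)
      file.path(s$label, paste0(s$roi_id,
                                if (nzchar(s$tag)) paste0("_", gsub("[^A-Za-z0-9.]+", "-", s$tag)) else "",
                                ".png")), character(1)),
    frame_id = vapply(samples, function(s) s$roi_id, character(1)),
    roi_id = vapply(samples, function(s) s$roi_id, character(1)),
    class_label = vapply(samples, function(s) s$label, character(1)),
    split = split,
    augmentation_tag = vapply(samples, function(s) s$tag, character(1)),
    row_start = NA_integer_, row_end = NA_integer_,
    col_start = NA_integer_, col_end = NA_integer_,
    stringsAsFactors = FALSE)
  df
}

#' Build a balanced train/test set with rarity and contrast expansion
#'
#' Base ROIs of each class are first split (seeded, uniform) into a
#' test reserve and a training pool at the base-ROI level, so no
#' variant of a test ROI can reach the training split. Test samples
#' stay unaugmented and unenhanced. The training pool is expanded by
#' the class's rarity recipe (originals plus recipe variants), then
#' uniformly subsampled to exactly `train_per_class`, and finally
#' expanded over the contrast levels (when `levels` is non-`NULL`),
#' giving `train_per_class * length(levels$deltas)` training samples
#' per class.
#'
#' @param samples List of base [labeled_sample()]s (unique `roi_id`s).
#' @param recipes Named list of [augmentation_recipe()]s keyed by
#'   class (classes without an entry get no rarity expansion).
#' @param levels A [contrast_levels()] set, or `NULL` to skip the
#'   contrast expansion.
#' @param train_per_class,test_per_class Exact per-class counts
#'   (defaults 2048 and 512) measured before the contrast expansion.
#' @param seed Integer seed controlling the split and subsampling.
#' @return List with `train`, `test` (sample lists) and `manifest`
#'   (combined manifest `data.frame`).
#' @export
build_training_set <- function(samples, recipes = default_recipes(),
                               levels = contrast_levels(),
                               train_per_class = 2048L,
                               test_per_class = 512L, seed = 17L) {
  labels <- vapply(samples, function(s) s$label, character(1))
  ids <- vapply(samples, function(s) s$roi_id, character(1))
  if (anyDuplicated(ids)) stop("base roi_ids must be unique")
  train <- list(); test <- list()
  deficits <- character()
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      base <- samples[labels == cl]
      base <- base[order(vapply(base, function(s) s$roi_id, character(1)))]
      perm <- sample.int(length(base))
      if (length(base) <= test_per_class) {
        deficits <- c(deficits, sprintf(
          "%s: %d base ROIs cannot fill %d test + a training pool",
          cl, length(base), test_per_class))
        next
      }
      te <- base[perm[seq_len(test_per_class)]]
      pool <- base[perm[-seq_len(test_per_class)]]
      rec <- recipes[[cl]]
      expanded <- pool
      if (!is.null(rec))
        for (s in pool) expanded <- c(expanded, apply_rarity_recipe(s, rec))
      if (length(expanded) < train_per_class) {
        deficits <- c(deficits, sprintf(
          "%s: %d post-recipe training samples < target %d",
          cl, length(expanded), train_per_class))
        next
      }
      tr <- expanded[sample.int(length(expanded), train_per_class)]
      if (!is.null(levels)) tr <- apply_contrast_levels(tr, levels)
      train <- c(train, tr)
      test <- c(test, te)
    }
  })
  if (length(deficits))
    stop("insufficient samples after augmentation:\n  ",
         paste(deficits, collapse = "\n  "))
  mf <- rbind(sample_manifest(train, "train"),
              sample_manifest(test, "test"))
  rownames(mf) <- NULL
  validate_manifest(mf)
  list(train = train, test = test, manifest = mf)
}
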