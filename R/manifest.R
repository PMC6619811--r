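#' Dataset manifests
#'
#' A manifest is a plain `data.frame` with one row per stored crop and
#' a fixed column order: `path`, `frame_id`, `roi_id`, `class_label`,
#' `split`, `augmentation_tag`, `row_start`, `row_end`, `col_start`,
#' `col_end`. Box coordinates are 0-based, half-open
#' `[row_start, row_end) x [col_start, col_end)`. Paths must be unique,
#' `split` is `"train"`, `"test"` or `""`, and no `roi_id` may appear
#' in both splits (augmented variants inherit the `roi_id` of their
#' base region, so split disjointness is a provenance guarantee).
#'
#' @param path,frame_id,roi_id,class_label,split,augmentation_tag
#'   Character vectors, recycled to a common length.
#' @param row_start,row_end,col_start,col_end Integer box bounds; `NA`
#'   when the crop has no frame of origin.
#' @return A validated manifest `data.frame`.
#' @export
manifest <- function(path = character(), frame_id = character(),
                     roi_id = character(), class_label = character(),
                     split = character(), augmentation_tag = character(),
                     row_start = NA_integer_, row_end = NA_integer_,
                     col_start = NA_integer_, col_end = NA_integer_) {
  n <- length(path)
  rl <- function(x) rep_len(x, n)
  df <- data.frame(path = as.character(path),
                   frame_id = rl(as.character(frame_id)),
                   roi_id = rl(as.character(roi_id)),
                   class_label = rl(as.character(class_label)),
                   split = rl(as.character(split)),
                   augmentation_tag = rl(as.character(augmentation_tag)),
                   row_start = rl(as.integer(row_start)),
                   row_end = rl(as.integer(row_end)),
                   col_start = rl(as.integer(col_start)),
                   col_end = rl(as.integer(col_end)),
                   stringsAsFactors = FALSE)
  validate_manifest(df)
  df
}

manifest_cols <- c("path", "frame_id", "roi_id", "class_label", "split",
                   "augmentation_tag", "row_start", "row_end",
                   "col_start", "col_end")

#' Validate a dataset manifest
#'
#' Checks column layout, path uniqueness, allowed split labels and
#' train/test disjointness at the `roi_id` level.
#'
#' @param df A manifest `data.frame`.
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_manifest <- function(df) {
  if (!all(manifest_cols %in% names(df)))
    stop("manifest is missing columns: ",
         paste(setdiff(manifest_cols, names(df)), collapse = ", "))
  if (anyDuplicated(df$path[nzchar(df$path)]))
    stop("manifest paths are not unique")
  bad <- setdiff(unique(df$split), c("train", "test", ""))
  if (length(bad))
    stop("invalid split labels: ", paste(bad, collapse = ", "))
  tr <- unique(df$roi_id[df$split == "train"])
  te <- unique(df$roi_id[df$split == "test"])
  both <- intersect(tr, te)
  if (length(both))
    stop("roi_id present in both splits: ",
         paste(head(both, 5), collapse = ", "))
  invisible(df)
}

#' Read / write a manifest CSV
#'
#' @param df A manifest `data.frame`.
#' @param path CSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the validated manifest.
#' @export
write_manifest <- function(df, path) {
  validate_manifest(df)
  write.csv(df[, manifest_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(rep("character", 6L), rep("integer", 4L)))
  validate_manifest(df)
  df
}

#' Save a set of ROIs as image files plus a manifest
#'
#' One image file is written per ROI (grayscale crop; the enhanced
#' crop is preferred when present) under `out_dir`, named by `roi_id`,
#' and a manifest CSV describing every file is written alongside.
#'
#' @param rois List of [roi()] objects with unique `roi_id`s.
#' @param out_dir Output directory (created if missing).
#' @param class_label,split,augmentation_tag Per-ROI metadata columns,
#'   recycled.
#' @param use_enhanced Prefer `enhanced_crop` over `gray_crop` when
#'   available (default `TRUE`).
#' @return The manifest `data.frame`, invisibly, with `path` filled in.
#' @export
save_roi_set <- function(rois, out_dir, class_label = "", split = "",
                         augmentation_tag = "", use_enhanced = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(rois, function(r) r$roi_id, character(1))
  if (anyDuplicated(ids))
    stop("roi_id collision: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(rois)
  class_label <- rep_len(as.character(class_label), max(n, 1L))
  split <- rep_len(as.character(split), max(n, 1L))
  augmentation_tag <- rep_len(as.character(augmentation_tag), max(n, 1L))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rois[[i]]
    crop <- if (use_enhanced && !is.null(r$enhanced_crop))
      r$enhanced_crop else r$gray_crop
    p <- save_frame(gray_frame(crop, frame_id = r$roi_id),
                    file.path(out_dir, r$roi_id))
    rows[[i]] <- data.frame(
      path = p, frame_id = r$frame_id, roi_id = r$roi_id,
      class_label = class_label[i], split = split[i],
      augmentation_tag = augmentation_tag[i],
      row_start = r$box["row_start"], row_end = r$box["row_end"],
      col_start = r$box["col_start"], col_end = r$box["col_end"],
      stringsAsFactors = FALSE)
  }
  df <- if (n) do.call(rbind, rows) else
    manifest()
  rownames(df) <- NULL
  validate_manifest(df)
  write_manifest(df, file.path(out_dir, "manifest.csv"))
  invisible(df)
}
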