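#' Region-of-interest container
#'
#' @param box A [bounding_box()] in frame coordinates.
#' @param gray_crop Integer intensity matrix of the box's extent.
#' @param mask_crop Logical matrix of the same shape with at least one
#'   `TRUE` pixel.
#' @param method Segmentation branch that produced the ROI
#'   (`"SAUVOLA"` or `"MSER"`).
#' @param frame_id Identifier of the source frame.
#' @param roi_id Unique identifier; defaults to
#'   `<frame_id>_roi<row_start>x<col_start>`.
#' @param enhanced_crop Optional enhanced intensity matrix (filled by
#'   [suppress_background()]).
#' @return An object of class `roi`.
#' @export
roi <- function(box, gray_crop, mask_crop, method = "SAUVOLA",
                frame_id = "frame", roi_id = NULL,
                enhanced_crop = NULL) {
  stopifnot(inherits(box, "bounding_box"))
  if (!identical(dim(gray_crop), dim(mask_crop)))
    stop("gray_crop and mask_crop dimensions differ")
  h <- box[["row_end"]] - box[["row_start"]]
  w <- box[["col_end"]] - box[["col_start"]]
  if (nrow(gray_crop) != h || ncol(gray_crop) != w)
    stop("crop dimensions do not match the bounding box")
  if (!any(mask_crop)) stop("mask_crop has no foreground pixel")
  if (is.null(roi_id))
    roi_id <- sprintf("%s_roi%dx%d", frame_id,
                      box[["row_start"]], box[["col_start"]])
  structure(list(box = box, gray_crop = gray_crop,
                 mask_crop = mask_crop, enhanced_crop = enhanced_crop,
                 method = method, frame_id = frame_id,
                 roi_id = roi_id),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s' %dx%d @(%d,%d) %s%s>\n", x$roi_id,
              nrow(x$gray_crop), ncol(x$gray_crop),
              x$box[["row_start"]], x$box[["col_start"]], x$method,
              if (!is.null(x$enhanced_crop)) " enhanced" else ""))
  invisible(x)
}

crop_matrix <- function(m, box) {
  m[(box[["row_start"]] + 1L):box[["row_end"]],
    (box[["col_start"]] + 1L):box[["col_end"]], drop = FALSE]
}

#' Segmentation configuration
#'
#' Bundles the parameters of the full extraction stage with the
#' defaults used throughout: MSNR routing threshold 0.1, Sauvola
#' `k = 0.34`, `R = 128`, window 2% of the frame side, bright
#' foreground polarity, minimum component area 25 px, IoU merge 0.2
#' and a merge gap of half the Sauvola window side.
#'
#' @param msnr_threshold Routing threshold (default 0.1).
#' @param sauvola A [sauvola_params()].
#' @param mser An [mser_config()].
#' @param denoise A [denoise_params()] for the breakpoint-connection
#'   cleanup; `NULL` disables the denoise stage.
#' @param min_area Minimum component area in pixels.
#' @param iou_merge,gap_px Box-merging parameters; `gap_px = NULL`
#'   derives half the Sauvola window side.
#' @return A `seg_config` list.
#' @export
seg_config <- function(msnr_threshold = 0.1, sauvola = sauvola_params(),
                       mser = mser_config(), denoise = denoise_params(),
                       min_area = 25L, iou_merge = 0.2, gap_px = NULL) {
  structure(list(msnr_threshold = msnr_threshold, sauvola = sauvola,
                 mser = mser, denoise = denoise,
                 min_area = as.integer(min_area),
                 iou_merge = iou_merge, gap_px = gap_px),
            class = "seg_config")
}

#' Extract regions of interest from a frame
#'
#' Routes the frame by its MSNR statistic ([compute_msnr()]): at or
#' below the threshold the single-pixel sliding Sauvola binarization
#' is used, above it the MSER branch (region masks unioned into one
#' binary mask). The mask is then cleaned and boundary-thickened by
#' the breakpoint-connection rule ([denoise_roughen()]), 8-connected
#' components at least `min_area` pixels become boxes, nearby boxes
#' are merged ([merge_boxes()]), and each box is cropped into a [roi()]
#' tagged with the branch that produced it.
#'
#' @param frame A [gray_frame()] or intensity matrix.
#' @param config A [seg_config()].
#' @return List of [roi()] objects (possibly empty).
#' @export
extract_rois <- function(frame, config = seg_config()) {
  if (is.matrix(frame)) frame <- gray_frame(frame)
  report <- compute_msnr(frame, threshold = config$msnr_threshold)
  if (report$route == "SAUVOLA") {
    mask <- binarize_sliding(frame, config$sauvola)
  } else {
    regs <- mser_regions(frame, config$mser)
    mask <- matrix(FALSE, frame$height, frame$width)
    for (r in regs) mask <- mask | r
  }
  if (!is.null(config$denoise))
    mask <- denoise_roughen(mask, config$denoise)
  boxes <- connected_components(mask, min_area = config$min_area)
  side <- window_side(min(frame$height, frame$width),
                      config$sauvola$window_frac)
  gap <- if (is.null(config$gap_px)) max(1L, side %/% 2L) else config$gap_px
  boxes <- merge_boxes(boxes, iou_merge = config$iou_merge, gap_px = gap)
  lapply(boxes, function(b)
    roi(b, crop_matrix(frame$pixels, b), crop_matrix(mask, b),
        method = report$route, frame_id = frame$frame_id))
}
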