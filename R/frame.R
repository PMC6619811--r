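#' Grayscale frame container
#'
#' A `gray_frame` holds a single-channel image as an integer matrix
#' (rows = image rows) together with its bit depth and the maximum
#' representable intensity `i_max` (255 for 8-bit, 65535 for 16-bit).
#'
#' @param pixels Numeric or integer matrix of intensities in
#'   `[0, i_max]`.
#' @param bit_depth Either 8 or 16.
#' @param frame_id Opaque identifier carried through the pipeline.
#' @return An object of class `gray_frame` with fields `pixels`,
#'   `height`, `width`, `bit_depth`, `i_max`, `frame_id`.
#' @examples
#' f <- gray_frame(matrix(0:255, 16, 16), frame_id = "ramp")
#' f$i_max
#' @export
gray_frame <- function(pixels, bit_depth = 8L, frame_id = "frame") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (length(pixels) == 0L) stop("zero-area image")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  i_max <- as.integer(2^bit_depth - 1)
  px <- round(pixels)
  if (anyNA(px)) stop("pixels contain NA")
  if (min(px) < 0 || max(px) > i_max)
    stop("intensities outside [0, ", i_max, "]")
  storage.mode(px) <- "integer"
  attributes(px) <- list(dim = dim(px))   # drop decoder metadata
  structure(
    list(pixels = px, height = nrow(px), width = ncol(px),
         bit_depth = as.integer(bit_depth), i_max = i_max,
         frame_id = as.character(frame_id)),
    class = "gray_frame")
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame '%s' %dx%d %d-bit, intensities %d..%d>\n",
              x$frame_id, x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# PNG bit depth lives in byte 25 of the file (8-byte signature, then
# the IHDR chunk: length 4, type 4, width 4, height 4, depth 1).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("truncated PNG: ", path)
  as.integer(hdr[25L])
}

# ITU-R BT.601 luminance weights for deterministic RGB collapse.
luminance_collapse <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3L]
  if (ch == 1L) return(arr[, , 1L])
  # channels beyond the third (alpha) are ignored
  0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
}

#' Load a frame from a PNG or TIFF file
#'
#' Color inputs are collapsed to luminance grayscale with the standard
#' ITU weights (0.299, 0.587, 0.114); the bit depth is taken from the
#' file (PNG header / TIFF `bits.per.sample`).
#'
#' @param path Path to an 8- or 16-bit PNG or TIFF file.
#' @param frame_id Identifier for the frame; defaults to the file name
#'   without extension.
#' @return A [gray_frame()].
#' @export
load_frame <- function(path, frame_id = NULL) {
  if (!file.exists(path)) stop("cannot read frame, no such file: ", path)
  if (is.null(frame_id))
    frame_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    depth <- png_bit_depth(path)
    arr <- png::readPNG(path)          # values scaled to [0, 1]
    bit_depth <- if (depth > 8L) 16L else 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    bit_depth <- if (!is.null(bps) && bps > 8L) 16L else 8L
  } else stop("unsupported image format: ", path)
  px <- luminance_collapse(arr) * (2^bit_depth - 1)
  if (length(px) == 0L) stop("zero-area image: ", path)
  gray_frame(px, bit_depth = bit_depth, frame_id = frame_id)
}

#' Save a frame (or plain intensity matrix) to disk
#'
#' 8-bit frames are written as PNG, 16-bit frames as TIFF, so that a
#' reload reproduces the pixels bit-exactly.
#'
#' @param frame A [gray_frame()] or an integer matrix (assumed 8-bit).
#' @param path Output path; the extension is forced to match the
#'   format chosen for the bit depth.
#' @return The path actually written, invisibly.
#' @export
save_frame <- function(frame, path) {
  if (is.matrix(frame)) frame <- gray_frame(frame)
  scaled <- frame$pixels / frame$i_max
  if (frame$bit_depth == 8L) {
    path <- sub("\\.[^.]+$", "", path)
    path <- paste0(path, ".png")
    png::writePNG(scaled, path)
  } else {
    path <- sub("\\.[^.]+$", "", path)
    path <- paste0(path, ".tif")
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  }
  invisible(path)
}
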