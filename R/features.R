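#' HOG configuration
#'
#' @param resize Canonical square side the crop is resized to before
#'   gradient computation (default 64).
#' @param cell Cell side in pixels (default 8).
#' @param block Block side in cells (default 2); blocks overlap with
#'   stride one cell and are L2-normalised.
#' @param bins Number of unsigned orientation bins over `[0, 180)`
#'   degrees (default 9).
#' @return A `hog_config` list.
#' @export
hog_config <- function(resize = 64L, cell = 8L, block = 2L, bins = 9L) {
  if (resize %% cell != 0L) stop("resize must be a multiple of cell")
  if (resize %/% cell < block) stop("crop too small for one block")
  structure(list(resize = as.integer(resize), cell = as.integer(cell),
                 block = as.integer(block), bins = as.integer(bins)),
            class = "hog_config")
}

hog_length <- function(config) {
  nb <- config$resize %/% config$cell - config$block + 1L
  nb * nb * config$block^2 * config$bins
}

#' Histogram-of-oriented-gradients descriptor
#'
#' The crop is resized to the canonical square, gradients are taken
#' with central differences (replicated borders), each pixel's
#' magnitude is assigned to one of `bins` unsigned orientation bins
#' over `[0, 180)` degrees, bin totals are accumulated per cell, and
#' overlapping `block x block` cell blocks (stride one cell) are
#' L2-normalised and concatenated. A constant crop yields the zero
#' vector; the descriptor length is fixed by the configuration alone.
#'
#' @param crop Integer intensity matrix (at least 2x2).
#' @param config A [hog_config()].
#' @param i_max Maximum representable intensity of the crop.
#' @return Numeric feature vector of length `blocks^2 * block^2 * bins`
#'   with attribute `extractor_id = "hog"`.
#' @export
hog_features <- function(crop, config = hog_config(), i_max = 255L) {
  if (!is.matrix(crop) || min(dim(crop)) < 2L)
    stop("degenerate crop: need at least 2x2 pixels")
  m <- resize_crop(crop, config$resize, i_max = i_max) / i_max
  n <- config$resize
  # central differences with replicated borders
  gx <- (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) / 2
  gy <- (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi          # (-180, 180]
  ang <- ang %% 180                        # unsigned [0, 180)
  bin <- pmin(floor(ang / (180 / config$bins)), config$bins - 1L) + 1L
  ncell <- n %/% config$cell
  cell_of <- function(i) (i - 1L) %/% config$cell + 1L
  crow <- cell_of(row(m)); ccol <- cell_of(col(m))
  # accumulate magnitude into (cell row, cell col, bin)
  idx <- (bin - 1L) * ncell * ncell + (ccol - 1L) * ncell + crow
  hist3 <- array(0, c(ncell, ncell, config$bins))
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  hist3[as.integer(names(acc))] <- acc
  nb <- ncell - config$block + 1L
  out <- numeric(nb * nb * config$block^2 * config$bins)
  k <- 0L
  blocklen <- config$block^2 * config$bins
  for (bc in seq_len(nb)) for (br in seq_len(nb)) {
    v <- as.vector(hist3[br:(br + config$block - 1L),
                         bc:(bc + config$block - 1L), ])
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    out[(k * blocklen + 1L):((k + 1L) * blocklen)] <- v
    k <- k + 1L
  }
  structure(out, extractor_id = "hog")
}

# ---- pluggable feature-extractor registry ----------------------------

.extractors <- new.env(parent = emptyenv())

#' Register or fetch a feature extractor
#'
#' An extractor is a function `f(crop, i_max)` returning a
#' fixed-length finite numeric vector. The built-in `"hog"` extractor
#' is always available; embedding back-ends (for example CNN
#' fully-connected outputs computed elsewhere) can be plugged in
#' under their own id.
#'
#' @param id Extractor identifier.
#' @param fn Extractor function (for `register_extractor`).
#' @return `register_extractor` returns `id` invisibly;
#'   `get_extractor` returns the function.
#' @export
register_extractor <- function(id, fn) {
  stopifnot(is.function(fn))
  assign(id, fn, envir = .extractors)
  invisible(id)
}

#' @rdname register_extractor
#' @export
get_extractor <- function(id) {
  if (id == "hog")
    return(function(crop, i_max = 255L) hog_features(crop, i_max = i_max))
  if (!exists(id, envir = .extractors))
    stop("unknown extractor id: ", id)
  get(id, envir = .extractors)
}

#' Extract a feature matrix from labeled samples
#'
#' Applies the extractor to every sample's crop and checks the
#' contract: every vector must have the same length and contain only
#' finite values.
#'
#' @param samples List of [labeled_sample()]s (or bare matrices).
#' @param extractor Extractor id (default `"hog"`) or function.
#' @return Numeric matrix (samples x features) with attribute
#'   `extractor_id`.
#' @export
extract_features <- function(samples, extractor = "hog") {
  id <- if (is.character(extractor)) extractor else "custom"
  fn <- if (is.character(extractor)) get_extractor(extractor) else extractor
  vecs <- lapply(samples, function(s) {
    crop <- if (inherits(s, "labeled_sample")) s$crop else s
    i_max <- if (inherits(s, "labeled_sample")) s$i_max else 255L
    v <- fn(crop, i_max)
    if (!all(is.finite(v))) stop("extractor '", id, "' returned non-finite values")
    v
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) > 1L)
    stop("extractor '", id, "' returned vectors of differing lengths: ",
         paste(unique(lens), collapse = ", "))
  x <- do.call(rbind, vecs)
  attr(x, "extractor_id") <- id
  x
}
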