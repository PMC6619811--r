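#' Sauvola binarization parameters
#'
#' @param k Fixed coefficient of the Sauvola formula (default 0.34).
#' @param R Maximum standard deviation that can occur; 128 for
#'   grayscale images.
#' @param window_frac Window side as a fraction of the shorter frame
#'   dimension, in `[0.01, 0.03]` (default 0.02). The derived side is
#'   `round(window_frac * min(height, width))`, forced odd, floor 3.
#' @param polarity `"BRIGHT_FG"` (default; pixels above threshold are
#'   foreground — bright organisms on a dark field) or `"DARK_FG"`
#'   (classical document polarity, pixels below threshold).
#' @return A `sauvola_params` list.
#' @export
sauvola_params <- function(k = 0.34, R = 128, window_frac = 0.02,
                           polarity = c("BRIGHT_FG", "DARK_FG")) {
  polarity <- match.arg(polarity)
  if (k <= 0) stop("k must be > 0")
  if (R <= 0) stop("R must be > 0")
  if (window_frac < 0.01 || window_frac > 0.03)
    stop("window_frac must lie in [0.01, 0.03]")
  structure(list(k = k, R = R, window_frac = window_frac,
                 polarity = polarity),
            class = "sauvola_params")
}

#' Window side length derived from a frame dimension
#'
#' `round(frac * shorter_side)`, forced odd so windows center exactly,
#' with a floor of 3.
#'
#' @param dim_min Shorter frame dimension in pixels.
#' @param window_frac Fraction in `[0.01, 0.03]`.
#' @return Odd integer side length, at least 3.
#' @export
window_side <- function(dim_min, window_frac = 0.02) {
  s <- round(window_frac * dim_min)
  s <- max(3L, as.integer(s))
  if (s %% 2L == 0L) s <- s + 1L
  s
}

#' Sauvola threshold of a pixel window
#'
#' \deqn{T = m \left[1 + k\left(\frac{\delta_w}{R} - 1\right)\right]}
#' with `m` the window mean and `delta_w` the window standard
#' deviation (population convention, divide by count). With a uniform
#' window (`delta_w = 0`) and `k = 0.34` this gives `T = 0.66 m`; when
#' `delta_w` reaches `R` it gives `T = m` exactly.
#'
#' @param window_pixels Numeric vector of window intensities.
#' @param params A [sauvola_params()].
#' @return The threshold intensity (numeric scalar).
#' @examples
#' sauvola_threshold(rep(100, 9), sauvola_params())         # 66
#' @export
sauvola_threshold <- function(window_pixels, params = sauvola_params()) {
  if (length(window_pixels) == 0L) stop("empty window")
  m <- mean(window_pixels)
  v <- mean(window_pixels^2) - m^2
  dw <- sqrt(max(v, 0))
  m * (1 + params$k * (dw / params$R - 1))
}

# Sum of `m` over the clipped window of half-width `rad` centered on
# every pixel, via running cumulative sums (exact, O(n)).
box_filter_sum <- function(m, rad) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2L, cumsum)
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  hi <- pmin(seq_len(nr) + rad, nr)
  lo <- seq_len(nr) - rad - 1L
  rowwin <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1L), nc),
          cs[lo[lo >= 1L], , drop = FALSE])
  cs2 <- t(apply(rowwin, 1L, cumsum))
  if (nc == 1L) cs2 <- t(cs2)
  hic <- pmin(seq_len(nc) + rad, nc)
  loc <- seq_len(nc) - rad - 1L
  cs2[, hic, drop = FALSE] -
    cbind(matrix(0, nr, sum(loc < 1L)),
          cs2[, loc[loc >= 1L], drop = FALSE])
}

# Local clipped-window mean and population sd for every pixel.
local_window_stats <- function(px, rad) {
  ones <- matrix(1, nrow(px), ncol(px))
  n <- box_filter_sum(ones, rad)
  s1 <- box_filter_sum(px, rad)
  s2 <- box_filter_sum(px^2, rad)
  m <- s1 / n
  v <- s2 / n - m^2
  list(mean = m, sd = sqrt(pmax(v, 0)), n = n)
}

#' Single-pixel sliding-window Sauvola binarization
#'
#' Centers a window on every pixel (sliding step 1 pixel), computes
#' the Sauvola threshold from the window's mean and standard
#' deviation, and binarizes only the central pixel. Windows are
#' clipped at frame edges (statistics over the intersection). The
#' result is identical to evaluating [sauvola_threshold()] pixel by
#' pixel.
#'
#' @param frame A [gray_frame()] or intensity matrix.
#' @param params A [sauvola_params()].
#' @param stride Sliding step in pixels. The default 1 binarizes every
#'   pixel; larger strides evaluate thresholds on a subgrid and fill
#'   each stride block with its center's decision (faster,
#'   approximate).
#' @return Logical matrix of the frame's shape (`TRUE` = foreground).
#' @export
binarize_sliding <- function(frame, params = sauvola_params(),
                             stride = 1L) {
  if (is.matrix(frame)) frame <- gray_frame(frame)
  px <- frame$pixels
  side <- window_side(min(dim(px)), params$window_frac)
  if (min(dim(px)) < 3L)
    stop("frame smaller than the minimum 3x3 window")
  rad <- (side - 1L) %/% 2L
  if (stride <= 1L) {
    st <- local_window_stats(px, rad)
    thr <- st$mean * (1 + params$k * (st$sd / params$R - 1))
    if (params$polarity == "BRIGHT_FG") px > thr else px < thr
  } else {
    ri <- seq(1L, nrow(px), by = stride)
    ci <- seq(1L, ncol(px), by = stride)
    st <- local_window_stats(px, rad)
    thr <- st$mean * (1 + params$k * (st$sd / params$R - 1))
    dec <- if (params$polarity == "BRIGHT_FG") px > thr else px < thr
    blockr <- rep(ri, each = stride, length.out = nrow(px))
    blockc <- rep(ci, each = stride, length.out = ncol(px))
    dec[blockr, blockc, drop = FALSE]
  }
}
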