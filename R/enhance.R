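#' Breakpoint-connection denoise parameters
#'
#' @param window_frac Window side as a fraction of the shorter mask
#'   dimension, in `[0.01, 0.03]` (default 0.02); derived side forced
#'   odd with a floor of 3.
#' @param cluster_frac Fraction of the window's valid pixels that must
#'   lie in a single 8-connected cluster (fixed at 0.75 in the
#'   procedure).
#' @return A `denoise_params` list.
#' @export
denoise_params <- function(window_frac = 0.02, cluster_frac = 0.75) {
  if (window_frac < 0.01 || window_frac > 0.03)
    stop("window_frac must lie in [0.01, 0.03]")
  if (cluster_frac <= 0 || cluster_frac > 1)
    stop("cluster_frac must lie in (0, 1]")
  structure(list(window_frac = window_frac, cluster_frac = cluster_frac),
            class = "denoise_params")
}

#' Adaptive valid-pixel threshold of a rectangular window
#'
#' The threshold equals the length of the window's diagonal minus 2:
#' \deqn{T_{value} = \lfloor\sqrt{2\,\lfloor\sqrt{N_{rect}}\rfloor^2}\rfloor - 2}
#' A pixel is a boundary feature point only when the number of valid
#' (white) pixels in its window reaches this count — genuine
#' boundaries run through the window, so they contribute at least a
#' diagonal's worth of pixels, whereas scattered noise does not.
#'
#' @param n_rect Number of pixels in the window (at least 9).
#' @return Integer threshold, nondecreasing in `n_rect`.
#' @examples
#' valid_pixel_threshold(100) # 12
#' valid_pixel_threshold(25)  # 5
#' @export
valid_pixel_threshold <- function(n_rect) {
  if (any(n_rect < 9)) stop("n_rect must be at least 9")
  side <- floor(sqrt(n_rect))
  as.integer(floor(sqrt(2 * side^2)) - 2)
}

# Size of the largest 8-connected cluster of TRUE cells in a small
# logical matrix, by iterated min-label propagation (no dependency;
# meant for window-sized inputs).
largest_cluster_size <- function(sub) {
  n_fg <- sum(sub)
  if (n_fg <= 1L) return(n_fg)
  nr <- nrow(sub); nc <- ncol(sub)
  lab <- matrix(0, nr, nc)
  lab[sub] <- as.numeric(which(sub))
  big <- as.numeric(nr * nc + 1)
  repeat {
    padded <- matrix(big, nr + 2L, nc + 2L)
    padded[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(sub, lab, big)
    nb <- pmin(
      padded[1:nr, 1:nc],         padded[1:nr, 2:(nc + 1L)],
      padded[1:nr, 3:(nc + 2L)],  padded[2:(nr + 1L), 1:nc],
      padded[2:(nr + 1L), 3:(nc + 2L)], padded[3:(nr + 2L), 1:nc],
      padded[3:(nr + 2L), 2:(nc + 1L)], padded[3:(nr + 2L), 3:(nc + 2L)])
    newlab <- ifelse(sub, pmin(lab, nb), 0)
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  max(tabulate(factor(lab[sub])))
}

#' Spatial-domain breakpoint-connection denoising and edge roughening
#'
#' Every pixel is re-decided from its centered rectangular window
#' (side = `window_frac` of the shorter mask dimension, forced odd,
#' floor 3; windows clipped at edges; `N_rect` is the nominal side
#' squared). A pixel becomes foreground iff
#'
#' 1. the count `N_valid` of foreground pixels inside its clipped
#'    centered window reaches [valid_pixel_threshold()]`(N_rect)`, and
#' 2. the largest 8-connected cluster of foreground pixels within the
#'    centered window, or within the union of the centered window and
#'    any one of its four side-adjacent windows (the rectangle
#'    extended by one window side up, down, left or right, clipped),
#'    contains at least `ceiling(cluster_frac * N_valid)` pixels.
#'
#' Clustered boundary pixels are retained and thickened (background
#' pixels adjacent to a dense cluster also satisfy the rule), while
#' scattered speckle fails the threshold or the clustering test and
#' is removed. No foreground is ever created in a window that
#' contains no input foreground.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param params A [denoise_params()].
#' @return Logical matrix of the same shape.
#' @export
denoise_roughen <- function(mask, params = denoise_params()) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask & TRUE
  nr <- nrow(mask); nc <- ncol(mask)
  s <- window_side(min(nr, nc), params$window_frac)
  rad <- (s - 1L) %/% 2L
  t_value <- valid_pixel_threshold(s * s)
  counts <- round(box_filter_sum(matrix(as.numeric(mask), nr, nc), rad))
  out <- matrix(FALSE, nr, nc)
  cand <- which(counts >= t_value)
  if (!length(cand)) return(out)
  rows <- (cand - 1L) %% nr + 1L
  cols <- (cand - 1L) %/% nr + 1L
  for (i in seq_along(cand)) {
    r <- rows[i]; cc <- cols[i]
    nv <- counts[cand[i]]
    need <- ceiling(params$cluster_frac * nv)
    r0 <- max(1L, r - rad); r1 <- min(nr, r + rad)
    c0 <- max(1L, cc - rad); c1 <- min(nc, cc + rad)
    sub <- mask[r0:r1, c0:c1, drop = FALSE]
    if (largest_cluster_size(sub) >= need) { out[cand[i]] <- TRUE; next }
    exts <- list(c(max(1L, r - rad - s), r1, c0, c1),   # up
                 c(r0, min(nr, r + rad + s), c0, c1),   # down
                 c(r0, r1, max(1L, cc - rad - s), c1),  # left
                 c(r0, r1, c0, min(nc, cc + rad + s)))  # right
    for (e in exts) {
      sub <- mask[e[1]:e[2], e[3]:e[4], drop = FALSE]
      if (largest_cluster_size(sub) >= need) { out[cand[i]] <- TRUE; break }
    }
  }
  out
}

#' Background suppression parameters
#'
#' @param delta Boundary parameter of the grayscale transform, in
#'   `[3, 4]` (default 3.7). `delta = 3` makes the transform the
#'   identity.
#' @return A `suppression_params` list.
#' @export
suppression_params <- function(delta = 3.7) {
  if (delta < 3 || delta > 4) stop("delta must lie in [3, 4]")
  structure(list(delta = delta), class = "suppression_params")
}

#' Boundary threshold of a background region
#'
#' \deqn{T_b = p_{min} + \frac{p_{max} - p_{min}}{\delta}}
#' computed over the nonzero background intensities.
#'
#' @param background_pixels Numeric vector of background intensities.
#' @param params A [suppression_params()].
#' @return The threshold intensity `T_b`.
#' @examples
#' background_threshold(c(10, 50, 110), suppression_params(3.7))
#' @export
background_threshold <- function(background_pixels,
                                 params = suppression_params()) {
  if (length(background_pixels) == 0L)
    stop("empty background region")
  p_min <- min(background_pixels)
  p_max <- max(background_pixels)
  p_min + (p_max - p_min) / params$delta
}

round_half_up <- function(x) floor(x + 0.5)

#' Suppress the background of an ROI by grayscale transformation
#'
#' Target pixels (where `mask_crop` is `TRUE`) are left unchanged.
#' Every *nonzero* background pixel `p` is replaced by
#' \deqn{p' = p + 5 (p - T_b)(\delta - 3),}
#' rounded half-up and clamped to `[0, i_max]`, where `T_b` is the
#' boundary threshold of the nonzero background
#' ([background_threshold()]). Background below the threshold is
#' darkened, background above it is amplified, so the target stands
#' out against its surround. Background pixels equal to exactly 0 are
#' excluded from `p_min`/`p_max` and left unchanged. At `delta = 3`
#' the transform is the identity, and `p = T_b` is a fixed point.
#'
#' @param x A [roi()] (fills `enhanced_crop`) or an intensity matrix
#'   (returns the transformed matrix; requires `mask`).
#' @param params A [suppression_params()].
#' @param mask Logical target mask when `x` is a matrix.
#' @param i_max Maximum representable intensity (default 255).
#' @return The ROI with `enhanced_crop` filled, or the transformed
#'   matrix.
#' @export
suppress_background <- function(x, params = suppression_params(),
                                mask = NULL, i_max = 255L) {
  if (inherits(x, "roi")) {
    enhanced <- suppress_background(x$gray_crop, params,
                                    mask = x$mask_crop, i_max = i_max)
    x$enhanced_crop <- enhanced
    return(x)
  }
  if (is.null(mask)) stop("mask is required for matrix input")
  px <- x
  bg <- !mask & px > 0
  if (!any(bg)) return(px)
  p <- px[bg]
  t_b <- background_threshold(p, params)
  p2 <- p + 5 * (p - t_b) * (params$delta - 3)
  px[bg] <- pmin(pmax(round_half_up(p2), 0), i_max)
  storage.mode(px) <- "integer"
  px
}

#' Full ROI enhancement
#'
#' Applies the breakpoint-connection denoise/roughen rule to the
#' ROI's mask and then background suppression to its grayscale crop;
#' deterministic. If denoising empties the mask, the original mask is
#' kept for the suppression step.
#'
#' @param x A [roi()].
#' @param dn A [denoise_params()].
#' @param sp A [suppression_params()].
#' @param i_max Maximum representable intensity.
#' @return The ROI with updated `mask_crop` and `enhanced_crop`.
#' @export
enhance_roi <- function(x, dn = denoise_params(),
                        sp = suppression_params(), i_max = 255L) {
  stopifnot(inherits(x, "roi"))
  cleaned <- denoise_roughen(x$mask_crop, dn)
  if (any(cleaned)) x$mask_crop <- cleaned
  suppress_background(x, sp, i_max = i_max)
}
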