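#' Frame contrast statistic and segmentation routing
#'
#' Computes the mean-signal-to-noise-ratio (MSNR) contrast statistic:
#' the maximum over pixels of the squared deviation from the frame
#' mean, normalised to the unit scale,
#' \deqn{MSNR = \max_i \left(\frac{M - x_i}{I_{max}}\right)^2,}
#' where `M` is the mean intensity and `I_max` the maximum
#' representable intensity (or, with `normalize = "observed"`, the
#' maximum observed intensity). Frames with MSNR at or below the
#' threshold are routed to the Sauvola branch (low contrast), frames
#' above it to the MSER branch (high contrast). A constant frame has
#' MSNR 0 and always routes to Sauvola.
#'
#' @param frame A [gray_frame()] or intensity matrix.
#' @param threshold Routing threshold on the unit-scaled statistic
#'   (default 0.1).
#' @param normalize `"representable"` (default) divides deviations by
#'   `i_max`; `"observed"` divides by the maximum observed intensity.
#' @return A `contrast_report`: list with `M` (mean intensity), `msnr`
#'   (in `[0, 1]`), `route` (`"SAUVOLA"` or `"MSER"`) and `threshold`.
#' @examples
#' f <- gray_frame(matrix(c(0, 100, 200), 30, 30))
#' compute_msnr(f)$route
#' @export
compute_msnr <- function(frame, threshold = 0.1,
                         normalize = c("representable", "observed")) {
  if (is.matrix(frame)) frame <- gray_frame(frame)
  normalize <- match.arg(normalize)
  px <- frame$pixels
  if (length(px) == 0L) stop("empty frame")
  M <- mean(px)
  denom <- if (normalize == "representable") frame$i_max
           else max(px, 1L)
  msnr <- max((M - range(px))^2) / denom^2
  structure(
    list(M = M, msnr = msnr,
         route = if (msnr > threshold) "MSER" else "SAUVOLA",
         threshold = threshold),
    class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("<contrast_report M=%.2f msnr=%.4f -> %s (threshold %.3g)>\n",
              x$M, x$msnr, x$route, x$threshold))
  invisible(x)
}
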