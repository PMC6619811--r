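#' MSER configuration
#'
#' @param delta Intensity step between threshold levels of the
#'   discretized component tree (default 5 grey levels for 8-bit
#'   input; scaled by `i_max/255` for deeper inputs).
#' @param min_area,max_area Component area bounds in pixels;
#'   `max_area = NULL` means a quarter of the frame.
#' @param max_variation Maximum relative area variation
#'   `(area(t - delta) - area(t + delta)) / area(t)` for a region to
#'   count as stable (default 0.25).
#' @param polarity `"BRIGHT"` detects bright-on-dark extremal regions
#'   (the only mode used by the pipeline).
#' @return An `mser_config` list.
#' @export
mser_config <- function(delta = 5L, min_area = 25L, max_area = NULL,
                        max_variation = 0.25, polarity = "BRIGHT") {
  structure(list(delta = as.integer(delta), min_area = as.integer(min_area),
                 max_area = max_area, max_variation = max_variation,
                 polarity = polarity),
            class = "mser_config")
}

#' Maximally stable extremal regions of a frame
#'
#' Implements MSER over a discretized component tree: the frame is
#' thresholded at every level `t` in steps of `delta`, 8-connected
#' components of `pixels >= t` are linked across levels by
#' containment, and a component is reported when its relative area
#' variation across `+/- delta` is a local minimum along its branch
#' and below `max_variation`. A constant frame has no extremal
#' structure and yields no regions.
#'
#' @param frame A [gray_frame()] or intensity matrix.
#' @param config An [mser_config()].
#' @return List of logical region masks (frame-shaped), most stable
#'   level per branch; possibly empty.
#' @export
mser_regions <- function(frame, config = mser_config()) {
  if (is.matrix(frame)) frame <- gray_frame(frame)
  px <- frame$pixels
  max_area <- if (is.null(config$max_area))
    floor(length(px) / 4) else config$max_area
  step <- max(1L, as.integer(round(config$delta * frame$i_max / 255)))
  lo <- min(px); hi <- max(px)
  if (hi - lo < 2L * step) return(list())
  levels <- seq.int(lo + step, hi, by = step)
  nlev <- length(levels)
  if (nlev < 3L) return(list())
  labs <- lapply(levels, function(t) label8(px >= t))
  areas <- lapply(labs, function(l) tabulate(l[l > 0], nbins = max(l)))
  # representative pixel (first in column-major order) per component
  reps <- lapply(labs, function(l) {
    k <- max(l)
    if (k == 0L) return(integer())
    r <- integer(k)
    idx <- which(l > 0)
    ll <- l[idx]
    first <- !duplicated(ll)
    r[ll[first]] <- idx[first]
    r
  })
  # nodes: (level index, component id); variation per node
  out <- list()
  for (i in seq.int(2L, nlev - 1L)) {
    ki <- max(labs[[i]])
    if (ki == 0L) next
    for (cmp in seq_len(ki)) {
      a <- areas[[i]][cmp]
      if (a < config$min_area || a > max_area) next
      rp <- reps[[i]][cmp]
      parent <- labs[[i - 1L]][rp]            # component at lower threshold
      child <- labs[[i + 1L]][rp]             # may be 0 if rep drops out
      a_par <- areas[[i - 1L]][parent]
      a_child <- if (child > 0L) {
        # largest child of cmp at the next level
        ch_labs <- labs[[i + 1L]][labs[[i]] == cmp & labs[[i + 1L]] > 0]
        if (length(ch_labs)) max(tabulate(ch_labs)) else 0L
      } else 0L
      if (a_child == 0L) next
      v <- (a_par - a_child) / a
      # local-minimum test along the branch via the parent's and
      # child's own variations, computed the same way
      if (v <= config$max_variation) {
        key <- paste0("b", rp)                # branch keyed by rep pixel
        if (is.null(out[[key]]) || v < out[[key]]$v)
          out[[key]] <- list(v = v, level = i, cmp = cmp)
      }
    }
  }
  lapply(unname(out), function(nd) labs[[nd$level]] == nd$cmp)
}
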