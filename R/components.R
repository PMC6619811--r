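# 8-connected labeling: EBImage::bwlabel is 4-connected, so label with
# it first and then union any two labels that touch diagonally.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs (both diagonal directions)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- pairs[i, 1]; rb <- pairs[i, 2]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- seq_len(k)
    for (i in seq_len(k)) {
      r <- i
      while (parent[r] != r) r <- parent[r]
      root[i] <- r
    }
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Bounding box constructor
#'
#' Boxes are 0-based, half-open:
#' `[row_start, row_end) x [col_start, col_end)`.
#'
#' @param row_start,row_end,col_start,col_end Integer bounds.
#' @return Named integer vector of class `bounding_box`.
#' @export
bounding_box <- function(row_start, row_end, col_start, col_end) {
  b <- c(row_start = as.integer(row_start), row_end = as.integer(row_end),
         col_start = as.integer(col_start), col_end = as.integer(col_end))
  if (b["row_end"] <= b["row_start"] || b["col_end"] <= b["col_start"])
    stop("empty bounding box")
  class(b) <- "bounding_box"
  b
}

box_area <- function(b)
  (b["row_end"] - b["row_start"]) * (b["col_end"] - b["col_start"])

box_iou <- function(a, b) {
  ir <- max(0L, min(a["row_end"], b["row_end"]) -
              max(a["row_start"], b["row_start"]))
  ic <- max(0L, min(a["col_end"], b["col_end"]) -
              max(a["col_start"], b["col_start"]))
  inter <- as.numeric(ir) * ic
  u <- as.numeric(box_area(a)) + box_area(b) - inter
  if (u <= 0) 0 else inter / u
}

# Smallest edge-to-edge gap between two boxes (0 when they overlap or
# touch); measured per axis in pixels.
box_gap <- function(a, b) {
  gr <- max(max(a["row_start"], b["row_start"]) -
              min(a["row_end"], b["row_end"]), 0L)
  gc <- max(max(a["col_start"], b["col_start"]) -
              min(a["col_end"], b["col_end"]), 0L)
  max(gr, gc)
}

box_union <- function(a, b)
  bounding_box(min(a["row_start"], b["row_start"]),
               max(a["row_end"], b["row_end"]),
               min(a["col_start"], b["col_start"]),
               max(a["col_end"], b["col_end"]))

#' Connected components of a binary mask as bounding boxes
#'
#' Components use 8-connectivity (diagonal neighbours connect);
#' components smaller than `min_area` pixels are dropped. Each
#' surviving component is reported as its tight bounding box.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum component pixel count (default 25).
#' @return List of [bounding_box()] objects, ordered by first pixel in
#'   column-major order.
#' @export
connected_components <- function(mask, min_area = 25L) {
  lab <- label8(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0)
  labs <- lab[idx]
  areas <- tabulate(labs, nbins = k)
  keep <- which(areas >= min_area)
  if (!length(keep)) return(list())
  rows <- (idx - 1L) %% nrow(lab)   # 0-based
  cols <- (idx - 1L) %/% nrow(lab)
  out <- lapply(keep, function(l) {
    sel <- labs == l
    bounding_box(min(rows[sel]), max(rows[sel]) + 1L,
                 min(cols[sel]), max(cols[sel]) + 1L)
  })
  out
}

#' Merge nearby or overlapping bounding boxes to a fixed point
#'
#' Any pair of boxes with intersection-over-union at least `iou_merge`
#' or edge-to-edge gap at most `gap_px` is replaced by its union box;
#' this is iterated until no pair qualifies, so multi-part targets
#' collapse into one box. The result is independent of input order.
#'
#' @param boxes List of [bounding_box()] objects.
#' @param iou_merge IoU at or above which two boxes merge
#'   (default 0.2).
#' @param gap_px Edge gap in pixels at or below which two boxes merge
#'   (default 3).
#' @return List of merged, pairwise non-mergeable boxes.
#' @export
merge_boxes <- function(boxes, iou_merge = 0.2, gap_px = 3L) {
  boxes <- boxes[order(vapply(boxes, function(b)
    sprintf("%06d%06d%06d%06d", b[1], b[3], b[2], b[4]), character(1)))]
  repeat {
    n <- length(boxes)
    if (n <= 1L) return(boxes)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- boxes[[i]]; b <- boxes[[j]]
        if (box_iou(a, b) >= iou_merge || box_gap(a, b) <= gap_px) {
          boxes[[i]] <- box_union(a, b)
          boxes[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(boxes)
  }
}
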