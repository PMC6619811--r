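# Independent brute-force oracles used across the test files. These
# deliberately share no code with the package internals: submatrix
# extraction, naive loops and a stack-based flood fill only.

# Per-pixel sliding Sauvola binarization, literal definition.
oracle_sauvola_mask <- function(px, k = 0.34, R = 128,
                                window_frac = 0.02,
                                bright = TRUE) {
  nr <- nrow(px); nc <- ncol(px)
  s <- max(3, round(window_frac * min(nr, nc)))
  if (s %% 2 == 0) s <- s + 1
  rad <- (s - 1) / 2
  out <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    w <- px[max(1, r - rad):min(nr, r + rad),
            max(1, c - rad):min(nc, c + rad)]
    m <- mean(w)
    dw <- sqrt(mean((w - m)^2))
    thr <- m * (1 + k * (dw / R - 1))
    out[r, c] <- if (bright) px[r, c] > thr else px[r, c] < thr
  }
  out
}

# Stack-based 8-connected flood fill; returns a label matrix.
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] > 0L) next
      lab[p] <- cur
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L)
          stack <- c(stack, (cc - 1L) * nr + rr)
      }
    }
  }
  lab
}

oracle_largest_cluster <- function(sub) {
  lab <- oracle_label8(sub)
  if (max(lab) == 0L) return(0L)
  max(tabulate(lab[lab > 0L]))
}

# Literal evaluation of the breakpoint-connection rule at every pixel.
oracle_denoise <- function(mask, window_frac = 0.02,
                           cluster_frac = 0.75) {
  nr <- nrow(mask); nc <- ncol(mask)
  s <- max(3, round(window_frac * min(nr, nc)))
  if (s %% 2 == 0) s <- s + 1
  rad <- (s - 1) / 2
  tv <- floor(sqrt(2 * floor(sqrt(s * s))^2)) - 2
  out <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    r0 <- max(1, r - rad); r1 <- min(nr, r + rad)
    c0 <- max(1, c - rad); c1 <- min(nc, c + rad)
    nv <- sum(mask[r0:r1, c0:c1])
    if (nv < tv) next
    need <- ceiling(cluster_frac * nv)
    regions <- list(
      c(r0, r1, c0, c1),
      c(max(1, r - rad - s), r1, c0, c1),
      c(r0, min(nr, r + rad + s), c0, c1),
      c(r0, r1, max(1, c - rad - s), c1),
      c(r0, r1, c0, min(nc, c + rad + s)))
    for (e in regions) {
      if (oracle_largest_cluster(
        mask[e[1]:e[2], e[3]:e[4], drop = FALSE]) >= need) {
        out[r, c] <- TRUE
        break
      }
    }
  }
  out
}

# Component bounding boxes via the flood-fill labels.
oracle_component_boxes <- function(mask, min_area = 1L) {
  lab <- oracle_label8(mask)
  out <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) < min_area) next
    r <- (idx - 1L) %% nrow(mask); c <- (idx - 1L) %/% nrow(mask)
    out[[length(out) + 1L]] <- c(row_start = min(r), row_end = max(r) + 1L,
                                 col_start = min(c), col_end = max(c) + 1L)
  }
  out
}

# Plain IoU between two boxes given as named vectors.
oracle_box_iou <- function(a, b) {
  ir <- max(0, min(a[["row_end"]], b[["row_end"]]) -
              max(a[["row_start"]], b[["row_start"]]))
  ic <- max(0, min(a[["col_end"]], b[["col_end"]]) -
              max(a[["col_start"]], b[["col_start"]]))
  inter <- ir * ic
  ua <- (a[["row_end"]] - a[["row_start"]]) *
    (a[["col_end"]] - a[["col_start"]])
  ub <- (b[["row_end"]] - b[["row_start"]]) *
    (b[["col_end"]] - b[["col_start"]])
  inter / (ua + ub - inter)
}

# Fraction of planted targets recovered at an IoU cutoff, plus the
# count of unmatched (false) ROIs.
match_rois <- function(rois, truth_boxes, iou_cut = 0.3) {
  matched <- logical(length(rois))
  rec <- 0L
  for (b in truth_boxes) {
    if (!length(rois)) next
    ious <- vapply(rois, function(x) oracle_box_iou(x$box, b), numeric(1))
    if (max(ious) >= iou_cut) {
      rec <- rec + 1L
      matched[which.max(ious)] <- TRUE
    }
  }
  list(recovered = rec, total = length(truth_boxes),
       false_rois = sum(!matched))
}

random_mask <- function(nr, nc, density = 0.1) {
  matrix(runif(nr * nc) < density, nr, nc)
}
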