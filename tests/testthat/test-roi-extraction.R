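test_that("sauvola threshold matches its closed forms", {
  p <- sauvola_params()
  expect_equal(sauvola_threshold(rep(100, 9), p), 66)
  # m = 100, population sd = 64 -> T = 100 * (1 + 0.34 * (0.5 - 1)) = 83
  w <- c(rep(100 - 64, 8), rep(100 + 64, 8))
  expect_equal(sauvola_threshold(w, p), 83)
  # sd = R -> threshold equals the window mean
  w2 <- c(rep(100 - 128, 8), rep(100 + 128, 8))
  expect_equal(sauvola_threshold(w2, p), 100)
})

test_that("sliding binarization equals the brute-force per-pixel oracle", {
  set.seed(31)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    got <- binarize_sliding(gray_frame(px))
    expect_identical(got, oracle_sauvola_mask(px))
  }
  # dark-foreground polarity too
  px <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  got <- binarize_sliding(gray_frame(px),
                          sauvola_params(polarity = "DARK_FG"))
  expect_identical(got, oracle_sauvola_mask(px, bright = FALSE))
})

test_that("constant bright frames binarize fully foreground", {
  m <- binarize_sliding(gray_frame(matrix(50, 20, 20)))
  expect_true(all(m))
})

test_that("local thresholding recovers a dim-half blob that a global threshold misses", {
  # two identical blobs under a strong illumination gradient on a
  # near-black field; the dim-side blob falls below a single global
  # threshold but not below the local one
  px <- matrix(0, 120, 120)
  blob <- function(r0, c0, val) {
    for (r in -6:6) for (c in -6:6)
      if (r^2 + c^2 <= 36) px[r0 + r, c0 + c] <<- val
  }
  blob(30, 30, 25)    # dim half
  blob(90, 90, 200)   # bright half
  f <- gray_frame(px)
  mask <- binarize_sliding(f)
  dim_cover <- mean(mask[24:36, 24:36][px[24:36, 24:36] > 0])
  bright_cover <- mean(mask[84:96, 84:96][px[84:96, 84:96] > 0])
  expect_gt(dim_cover, 0.9)
  expect_gt(bright_cover, 0.9)
  thr <- EBImage::otsu(px / 255) * 255
  global <- px > thr
  expect_lt(mean(global[24:36, 24:36][px[24:36, 24:36] > 0]), 0.1)
})

test_that("mser finds no regions in constant frames and one region for a disk", {
  expect_length(mser_regions(gray_frame(matrix(9, 40, 40))), 0L)
  px <- matrix(0, 64, 64)
  for (r in 1:64) for (c in 1:64)
    if ((r - 32)^2 + (c - 32)^2 <= 100) px[r, c] <- 180
  regs <- mser_regions(gray_frame(px))
  expect_length(regs, 1L)
  truth <- px > 0
  expect_lt(abs(sum(regs[[1]]) - sum(truth)) / sum(truth), 0.1)
})

test_that("mser resolves nested plateaus into the analytically stable regions", {
  px <- matrix(0, 64, 64)
  px[10:30, 10:30] <- 100
  px[15:25, 15:25] <- 200
  regs <- mser_regions(gray_frame(px))
  areas <- sort(vapply(regs, sum, numeric(1)))
  expect_identical(areas, c(121, 441))   # inner 11x11, outer 21x21
  inner <- regs[[which.min(vapply(regs, sum, numeric(1)))]]
  expect_true(all(which(inner) %in% which(px == 200)))
})

test_that("connected components agree with a flood-fill oracle and use 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[3, 3] <- TRUE; m[4, 4] <- TRUE     # diagonal touch
  expect_length(connected_components(m, min_area = 1), 1L)

  m2 <- matrix(FALSE, 12, 12); m2[4:8, 5:9] <- TRUE
  box <- connected_components(m2, min_area = 1)[[1]]
  expect_identical(unclass(box),
                   c(row_start = 3L, row_end = 8L,
                     col_start = 4L, col_end = 9L))

  set.seed(41)
  for (i in 1:8) {
    mk <- random_mask(30, 30, density = 0.12)
    got <- connected_components(mk, min_area = 2)
    want <- oracle_component_boxes(mk, min_area = 2)
    canon <- function(bs) {
      if (!length(bs)) return(character())
      sort(vapply(bs, function(b) paste(b, collapse = ","), character(1)))
    }
    expect_identical(canon(got), canon(want))
  }
})

test_that("box merging unions overlapping pairs and closes chains", {
  b1 <- bounding_box(0, 10, 0, 10)
  far <- bounding_box(50, 60, 50, 60)
  expect_length(merge_boxes(list(b1, far), gap_px = 2), 2L)

  # IoU((0,10)x(0,10), (0,10)x(5,15)) = 50/150 = 1/3 >= 0.3
  b2 <- bounding_box(0, 10, 5, 15)
  got <- merge_boxes(list(b1, b2), iou_merge = 0.3, gap_px = 0)
  expect_length(got, 1L)
  expect_identical(unclass(got[[1]]),
                   unclass(bounding_box(0, 10, 0, 15)))

  # chain A-B-C where only adjacent pairs are within the gap
  a <- bounding_box(0, 10, 0, 10)
  b <- bounding_box(0, 10, 12, 22)
  c_ <- bounding_box(0, 10, 24, 34)
  got <- merge_boxes(list(a, b, c_), iou_merge = 0.99, gap_px = 2)
  expect_length(got, 1L)
  expect_identical(unclass(got[[1]]),
                   unclass(bounding_box(0, 10, 0, 34)))
})

test_that("merging reaches a fixed point and is independent of input order", {
  set.seed(51)
  for (i in 1:6) {
    boxes <- lapply(1:8, function(j) {
      r <- sample(0:40, 1); c <- sample(0:40, 1)
      bounding_box(r, r + sample(5:15, 1), c, c + sample(5:15, 1))
    })
    out <- merge_boxes(boxes, iou_merge = 0.2, gap_px = 3)
    # fixed point: no surviving pair still qualifies
    if (length(out) > 1)
      for (p in seq_len(length(out) - 1)) for (q in (p + 1):length(out)) {
        expect_lt(oracle_box_iou(out[[p]], out[[q]]), 0.2)
      }
    again <- merge_boxes(out, iou_merge = 0.2, gap_px = 3)
    expect_identical(again, out)
    shuffled <- merge_boxes(boxes[sample(length(boxes))],
                            iou_merge = 0.2, gap_px = 3)
    canon <- function(bs) sort(vapply(bs, function(b)
      paste(b, collapse = ","), character(1)))
    expect_identical(canon(shuffled), canon(out))
  }
})

test_that("extraction recovers planted low-contrast targets and skips blank scenes", {
  sc <- render_scene(scene_preset("hard", n_targets = 5, seed = 3))
  rois <- extract_rois(sc$frame)
  m <- match_rois(rois, sc$boxes)
  expect_gte(m$recovered, 4L)
  expect_lte(m$false_rois, 1L)
  expect_true(all(vapply(rois, function(r) r$method, "") == "SAUVOLA"))
  # boxes stay within frame bounds
  for (r in rois) {
    expect_gte(r$box[["row_start"]], 0L)
    expect_lte(r$box[["row_end"]], sc$frame$height)
    expect_gte(r$box[["col_start"]], 0L)
    expect_lte(r$box[["col_end"]], sc$frame$width)
  }

  blank <- render_scene(scene_spec(height = 128, width = 128, seed = 9))
  expect_length(extract_rois(blank$frame), 0L)

  easy <- render_scene(scene_preset("easy", n_targets = 3, seed = 4))
  easy_rois <- extract_rois(easy$frame)
  expect_gt(length(easy_rois), 0L)
  expect_true(all(vapply(easy_rois, function(r) r$method, "") == "MSER"))
})

test_that("extraction is deterministic for a fixed config", {
  sc <- render_scene(scene_preset("hard", seed = 12))
  r1 <- extract_rois(sc$frame)
  r2 <- extract_rois(sc$frame)
  expect_identical(r1, r2)
})
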