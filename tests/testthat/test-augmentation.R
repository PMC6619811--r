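make_sample <- function(label = "euphausiids", n = 20, seed = 1,
                        id = "s1") {
  set.seed(seed)
  crop <- matrix(sample(0:255, n * n, TRUE), n, n)
  mask <- matrix(FALSE, n, n)
  mask[3:(n - 2), 3:(n - 2)] <- TRUE
  labeled_sample(crop, label, mask = mask, roi_id = id)
}

test_that("rarity recipes yield 3, 4 and 5 variants and reject class mismatch", {
  rec <- default_recipes()
  expect_length(apply_rarity_recipe(make_sample("euphausiids"),
                                    rec$euphausiids), 3L)
  expect_length(apply_rarity_recipe(make_sample("chaetognatha"),
                                    rec$chaetognatha), 4L)
  expect_length(apply_rarity_recipe(make_sample("fish_larvae"),
                                    rec$fish_larvae), 5L)
  expect_error(apply_rarity_recipe(make_sample("copepoda"),
                                   rec$euphausiids), "does not apply")
  expect_error(augmentation_recipe("bad", c("ROT90_CW", "ROT90_CW"), "x"),
               "at most once")
})

test_that("geometric ops are intensity-preserving permutations with the right algebra", {
  s <- make_sample(n = 15)
  vars <- apply_rarity_recipe(s, default_recipes()$euphausiids)
  for (v in vars[1:3]) {   # rotations/mirror: same histogram
    expect_identical(sort(as.vector(v$crop)), sort(as.vector(s$crop)))
    expect_identical(sum(v$mask), sum(s$mask))
  }
  r90 <- planktonseg:::rot90_cw
  expect_identical(r90(r90(r90(r90(s$crop)))), s$crop)
  expect_identical(r90(r90(s$crop)), planktonseg:::rot180_cw(s$crop))
  ud <- planktonseg:::mirror_ud
  lr <- planktonseg:::mirror_lr
  expect_identical(ud(ud(s$crop)), s$crop)
  expect_identical(lr(lr(s$crop)), s$crop)
})

test_that("contrast widening stretches to the full dynamic range", {
  s <- make_sample("fish_larvae")
  s$crop <- matrix(as.integer(seq(40, 90, length.out = 100)), 10, 10)
  v <- planktonseg:::apply_op(s, "CONTRAST_WIDEN")
  expect_identical(min(v$crop), 0L)
  expect_identical(max(v$crop), 255L)
  expect_identical(dim(v$crop), dim(s$crop))
})

test_that("contrast-level expansion multiplies counts and is identity at delta 3", {
  lv <- contrast_levels()
  expect_identical(lv$deltas, c(3.1, 3.3, 3.5, 3.7, 3.9))
  expect_error(contrast_levels(c(3.1, 4.2)), "\\[3, 4\\]")
  samples <- lapply(1:4, function(i) make_sample(seed = i, id = paste0("s", i)))
  out <- apply_contrast_levels(samples, lv)
  expect_length(out, 20L)
  expect_length(apply_contrast_levels(list(), lv), 0L)
  one <- apply_contrast_levels(samples[1], contrast_levels(3.0))
  expect_identical(one[[1]]$crop, matrix(as.integer(samples[[1]]$crop),
                                         nrow(samples[[1]]$crop)))
  nomask <- labeled_sample(samples[[1]]$crop, "other")
  expect_error(apply_contrast_levels(list(nomask), lv), "mask")
})

test_that("balanced builds hit exact counts with disjoint provenance, deterministically", {
  base <- list()
  for (cl in c("euphausiids", "copepoda")) {
    for (i in 1:24)
      base <- c(base, list(make_sample(cl, n = 12, seed = i * 7,
                                       id = sprintf("%s%02d", cl, i))))
  }
  # euphausiids: 16 pool x (1+3) = 64; copepoda has no recipe: pool 16 >= 16
  bt <- build_training_set(base, levels = contrast_levels(),
                           train_per_class = 16, test_per_class = 8,
                           seed = 2)
  expect_length(bt$test, 16L)                 # 8 per class
  expect_length(bt$train, 2L * 16L * 5L)      # levels expansion
  validate_manifest(bt$manifest)
  tr_ids <- unique(bt$manifest$roi_id[bt$manifest$split == "train"])
  te_ids <- unique(bt$manifest$roi_id[bt$manifest$split == "test"])
  expect_length(intersect(tr_ids, te_ids), 0L)

  bt2 <- build_training_set(base, levels = contrast_levels(),
                            train_per_class = 16, test_per_class = 8,
                            seed = 2)
  expect_identical(bt$manifest, bt2$manifest)

  expect_error(
    build_training_set(base, levels = contrast_levels(),
                       train_per_class = 200, test_per_class = 8, seed = 2),
    "insufficient")
})
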