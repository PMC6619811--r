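test_that("hog descriptor honours its shape contract and zero-gradient case", {
  cfg <- hog_config()
  d <- planktonseg:::hog_length(cfg)
  flat <- hog_features(matrix(120L, 30, 30))
  expect_length(flat, d)
  expect_true(all(flat == 0))
  set.seed(71)
  for (i in 1:4) {
    crop <- matrix(sample(0:255, 40 * 50, TRUE), 40, 50)
    expect_length(hog_features(crop), d)
  }
  expect_error(hog_features(matrix(1L, 1, 1)), "degenerate")
})

test_that("hog norms are preserved under 180-degree rotation", {
  set.seed(72)
  for (i in 1:3) {
    crop <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    v1 <- hog_features(crop)
    v2 <- hog_features(planktonseg:::rot180_cw(crop))
    expect_equal(sqrt(sum(v1^2)), sqrt(sum(v2^2)), tolerance = 1e-8)
  }
})

test_that("the extractor registry enforces the fixed-length finite contract", {
  set.seed(73)
  samples <- lapply(1:5, function(i)
    labeled_sample(matrix(sample(0:255, 100, TRUE), 10, 10), "other",
                   roi_id = paste0("x", i)))
  x <- extract_features(samples, "hog")
  expect_identical(dim(x)[1], 5L)
  expect_identical(attr(x, "extractor_id"), "hog")

  register_extractor("mean1", function(crop, i_max) mean(crop) / i_max)
  x1 <- extract_features(samples, "mean1")
  expect_identical(dim(x1), c(5L, 1L))

  register_extractor("broken", function(crop, i_max)
    numeric(sample(2:3, 1)))
  expect_error(extract_features(samples, "broken"), "differing lengths")
  register_extractor("nonfinite", function(crop, i_max) c(1, NaN))
  expect_error(extract_features(samples, "nonfinite"), "non-finite")
  expect_error(extract_features(samples, "nope"), "unknown extractor")
})

sep_clusters <- function(n_per, k, d = 4, sd = 0.05, seed = 74) {
  set.seed(seed)
  x <- NULL; y <- character()
  for (i in seq_len(k)) {
    mu <- rep(0, d); mu[(i - 1) %% d + 1] <- 3 * ((i - 1) %/% d + 1)
    x <- rbind(x, matrix(rnorm(n_per * d, 0, sd), n_per, d) +
                 matrix(mu, n_per, d, byrow = TRUE))
    y <- c(y, rep(sprintf("class%02d", i), n_per))
  }
  list(x = x, y = y)
}

test_that("the one-vs-one ensemble has k(k-1)/2 members and separates clusters", {
  two <- sep_clusters(10, 2)
  ens2 <- train_ovo_svm(two$x, two$y)
  expect_length(ens2$pairs, 1L)

  seven <- sep_clusters(12, 7)
  ens7 <- train_ovo_svm(seven$x, seven$y)
  expect_length(ens7$pairs, 21L)
  pred <- predict(ens7, seven$x)
  expect_identical(pred$label, seven$y)        # 100% on separable training data
  expect_identical(dim(pred$scores), c(nrow(seven$x), 7L))

  expect_error(train_ovo_svm(two$x[1:10, ], two$y[1:10]), "two classes")
  expect_error(predict(ens7, matrix(0, 1, 9)), "does not match")
})

test_that("prediction is deterministic and ties break to the smaller label", {
  seven <- sep_clusters(8, 3)
  ens <- train_ovo_svm(seven$x, seven$y)
  p1 <- predict(ens, seven$x)
  p2 <- predict(ens, seven$x)
  expect_identical(p1, p2)

  # zero-weight ensemble: every pairwise probability is 1/2, all class
  # scores tie, so the lexicographically smallest label must win
  flat <- ens
  flat$pairs <- lapply(flat$pairs, function(p) {
    p$W[] <- 0; p$b <- 0; p$cal_a <- 0; p$cal_b <- 0; p
  })
  pf <- predict(flat, seven$x[1:3, ])
  expect_true(all(pf$label == sort(ens$classes)[1]))

  # majority voting is available and agrees on separable data
  pm <- predict(ens, seven$x, voting = "majority")
  expect_identical(pm$label, p1$label)
})

test_that("evaluation reports match hand-computed contingencies", {
  seven <- sep_clusters(8, 3)
  ens <- train_ovo_svm(seven$x, seven$y)
  rep <- evaluate_classifier(ens, seven$x, seven$y)
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$macro_precision), 1)
  expect_true(all(diag(rep$confusion) == 8))
  expect_identical(rowSums(rep$confusion), colSums(rep$confusion))

  # 2-class outcome with TP=3, FP=1, FN=1 for class a
  ens2 <- list(classes = c("a", "b"),
               pairs = list(list(class_a = "a", class_b = "b",
                                 W = 1, b = 0, cal_a = 0, cal_b = 5)),
               cost = 1, n_features = 1L, extractor_id = "raw")
  class(ens2) <- "ovo_svm"
  x <- matrix(c(1, 1, 1, -1, 1, -1, -1, -1), ncol = 1)
  y <- c("a", "a", "a", "a", "b", "b", "b", "b")
  rep2 <- evaluate_classifier(ens2, x, y)
  expect_equal(unname(rep2$precision["a"]), 0.75)
  expect_equal(unname(rep2$recall["a"]), 0.75)
  # row sums conserve the per-class test counts
  expect_identical(unname(rowSums(rep2$confusion)), c(4, 4))
  # macro values recompute from the stored confusion matrix
  cm <- rep2$confusion
  expect_equal(rep2$macro_precision, mean(diag(cm) / colSums(cm)))
  expect_equal(rep2$macro_recall, mean(diag(cm) / rowSums(cm)))

  # all-wrong predictions give zero macro scores
  yflip <- ifelse(y == "a", "b", "a")
  x2 <- x
  rep3 <- evaluate_classifier(ens2, x2, yflip)
  expect_equal(rep3$accuracy, 0.25) # 2 of 8 right by the flip asymmetry
  expect_error(evaluate_classifier(ens2, x, c(y[-1], "c")), "outside")
})

test_that("replicate-averaged evaluation returns means over reseeded runs", {
  seven <- sep_clusters(8, 3)
  out <- evaluate_replicates(seven$x, seven$y, seven$x, seven$y,
                             n_replicates = 2L)
  expect_length(out$reports, 2L)
  expect_equal(out$accuracy, 1)
})
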