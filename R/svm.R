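#' Train a one-vs-one multi-class linear SVM ensemble
#'
#' One linear max-margin classifier `f(X) = W'X + b` is trained per
#' unordered class pair — `k(k-1)/2` classifiers for `k` classes —
#' and each is given a deterministic Platt-style probability
#' calibration: a logistic fit of class membership on the training
#' decision values. Prediction aggregates the calibrated pairwise
#' probabilities per class and takes the argmax
#' ([predict.ovo_svm()]).
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Class labels (character or factor), at least two
#'   classes with at least two samples each.
#' @param cost Soft-margin cost `C` (default 1).
#' @param seed Seed for any stochastic step (kept for interface
#'   stability; the fit itself is deterministic).
#' @return An object of class `ovo_svm` with fields `classes`,
#'   `pairs` (list of pairwise classifiers with `class_a`, `class_b`,
#'   `W`, `b`, calibration coefficients), `cost`, `extractor_id`.
#' @export
train_ovo_svm <- function(features, labels, cost = 1, seed = 17L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least two classes, got ", length(classes))
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least two samples")
  pairs <- list()
  with_seed(seed, {
    for (i in seq_len(length(classes) - 1L)) {
      for (j in seq.int(i + 1L, length(classes))) {
        a <- classes[i]; b <- classes[j]
        sel <- labels %in% c(a, b)
        x <- features[sel, , drop = FALSE]
        y <- factor(labels[sel], levels = c(a, b))
        fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                          scale = FALSE)
        w <- crossprod(fit$coefs, fit$SV)[1L, ]
        b0 <- -fit$rho
        dec <- drop(x %*% w) + b0
        # decision > 0 corresponds to the first factor level (class a)
        cal <- platt_calibrate(dec, y == a)
        pairs[[length(pairs) + 1L]] <- list(
          class_a = a, class_b = b, W = w, b = b0,
          cal_a = cal[1L], cal_b = cal[2L])
      }
    }
  })
  structure(list(classes = classes, pairs = pairs, cost = cost,
                 n_features = ncol(features),
                 extractor_id = attr(features, "extractor_id")),
            class = "ovo_svm")
}

# Logistic (Platt-style) calibration of decision values; returns
# c(intercept, slope). The glm absorbs the sign convention of the
# decision values; with perfect separation (glm divergence) a steep
# sigmoid oriented by the class means is used instead.
platt_calibrate <- function(dec, is_a) {
  fit <- suppressWarnings(try(
    glm(is_a ~ dec, family = binomial()), silent = TRUE))
  if (inherits(fit, "try-error") || !fit$converged ||
      any(!is.finite(coef(fit)))) {
    sc <- max(sd(dec), 1e-6)
    orient <- if (mean(dec[is_a]) >= mean(dec[!is_a])) 1 else -1
    mid <- (mean(dec[is_a]) + mean(dec[!is_a])) / 2
    return(c(-orient * 4 * mid / sc, orient * 4 / sc))
  }
  unname(coef(fit))
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf(
    "<ovo_svm: %d classes, %d pairwise linear classifiers, C=%g, %d features>\n",
    length(x$classes), length(x$pairs), x$cost, x$n_features))
  invisible(x)
}

#' @export
summary.ovo_svm <- function(object, ...) {
  print(object)
  cat("classes:", paste(object$classes, collapse = ", "), "\n")
  invisible(object)
}

#' Predict classes by pairwise probability voting
#'
#' Every pairwise classifier evaluates its decision value, maps it
#' through its calibration to a probability for its two classes, and
#' each class accumulates the probabilities from the `k-1` pairs it
#' participates in. The predicted label is the class with the highest
#' accumulated score; exact ties go to the lexicographically smaller
#' label.
#'
#' @param object An [train_ovo_svm()] ensemble.
#' @param newdata Feature matrix (samples x features) or a single
#'   feature vector.
#' @param voting `"probability"` (default) sums calibrated pairwise
#'   probabilities; `"majority"` counts pairwise wins instead.
#' @param ... Unused.
#' @return List with `label` (character vector) and `scores` (samples
#'   x classes matrix of accumulated scores).
#' @export
predict.ovo_svm <- function(object, newdata,
                            voting = c("probability", "majority"), ...) {
  voting <- match.arg(voting)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$n_features)
    stop("feature length ", ncol(newdata), " does not match ensemble (",
         object$n_features, ")")
  scores <- matrix(0, nrow(newdata), length(object$classes),
                   dimnames = list(NULL, object$classes))
  for (p in object$pairs) {
    dec <- drop(newdata %*% p$W) + p$b
    if (voting == "probability") {
      pa <- 1 / (1 + exp(-(p$cal_a + p$cal_b * dec)))
      scores[, p$class_a] <- scores[, p$class_a] + pa
      scores[, p$class_b] <- scores[, p$class_b] + (1 - pa)
    } else {
      win_a <- dec > 0
      scores[, p$class_a] <- scores[, p$class_a] + win_a
      scores[, p$class_b] <- scores[, p$class_b] + !win_a
    }
  }
  # ties resolved toward the lexicographically smaller label because
  # classes are sorted and max.col takes the first maximum
  lab <- object$classes[max.col(scores, ties.method = "first")]
  list(label = lab, scores = scores)
}

#' Evaluate an ensemble on a labeled test set
#'
#' @param ensemble An [train_ovo_svm()] ensemble.
#' @param features Test feature matrix.
#' @param labels True labels (must all be ensemble classes).
#' @return An `evaluation_report`: `confusion` (true x predicted
#'   counts), per-class `precision` and `recall`
#'   (`TP/(TP+FP)`, `TP/(TP+FN)`; `NA` when undefined),
#'   `macro_precision`, `macro_recall`, `accuracy`, `n`.
#' @export
evaluate_classifier <- function(ensemble, features, labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty test set")
  bad <- setdiff(unique(labels), ensemble$classes)
  if (length(bad))
    stop("labels outside ensemble classes: ", paste(bad, collapse = ", "))
  pred <- predict(ensemble, features)$label
  cls <- ensemble$classes
  confusion <- table(factor(labels, levels = cls),
                     factor(pred, levels = cls))
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 0)
  recall <- tp / pmax(rowSums(confusion), 0)
  precision[colSums(confusion) == 0] <- NA
  recall[rowSums(confusion) == 0] <- NA
  structure(
    list(confusion = unclass(confusion),
         precision = precision, recall = recall,
         macro_precision = mean(precision, na.rm = TRUE),
         macro_recall = mean(recall, na.rm = TRUE),
         accuracy = sum(tp) / length(labels), n = length(labels)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report n=%d accuracy=%.4f macroP=%.4f macroR=%.4f>\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall))
  invisible(x)
}

#' Replicate-averaged evaluation
#'
#' Retrains the ensemble `n_replicates` times under derived seeds and
#' averages accuracy, macro precision and macro recall over the
#' replicates.
#'
#' @param train_features,train_labels Training data.
#' @param test_features,test_labels Held-out data.
#' @param n_replicates Number of reseeded training runs (default 5).
#' @param cost Soft-margin cost.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @return List with mean `accuracy`, `macro_precision`,
#'   `macro_recall` and the per-replicate `reports`.
#' @export
evaluate_replicates <- function(train_features, train_labels,
                                test_features, test_labels,
                                n_replicates = 5L, cost = 1, seed = 17L) {
  reports <- lapply(seq_len(n_replicates), function(r) {
    ens <- train_ovo_svm(train_features, train_labels, cost = cost,
                         seed = seed + r)
    evaluate_classifier(ens, test_features, test_labels)
  })
  list(accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
       macro_precision = mean(vapply(reports, `[[`, numeric(1),
                                     "macro_precision")),
       macro_recall = mean(vapply(reports, `[[`, numeric(1),
                                  "macro_recall")),
       reports = reports)
}
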