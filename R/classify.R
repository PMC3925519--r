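# Linear classifier: y = f(w . x) with one discriminant per class and an
# argmax decision. Two trainers are provided; both are linear in the feature
# vector and store explicit per-class weight vectors (bias first), so a
# fitted model is stateless and serializable.
#
#   * "lda": multiclass linear discriminant analysis with pooled within-class
#     covariance (the classical "linear classifier"); discriminant for class k
#     is x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k.
#   * "lsq": least squares regression onto a class-indicator matrix.
#
# A singular pooled scatter (or Gram) matrix falls back to a ridge-regularized
# solve with a warning.

#' Fit a linear classifier
#'
#' Trains one linear discriminant per class from labeled feature vectors; the
#' predicted class is the argmax of the discriminant scores, with ties broken
#' deterministically toward the lowest class index.
#'
#' @param x Numeric matrix, one feature vector per row. Column names become
#'   the model's expected feature order.
#' @param labels Class label per row (coerced to character).
#' @param method Trainer: `"lda"` (pooled-covariance linear discriminant
#'   analysis, the default) or `"lsq"` (least squares onto class indicators).
#' @param standardize If `TRUE`, features are z-scored using training-set
#'   statistics that are stored in the model and re-applied at prediction.
#' @param ridge Relative ridge added to a numerically singular scatter/Gram
#'   matrix (scaled by its mean diagonal) as a fallback.
#' @return An object of class `linear_classifier` with elements
#'   `class_labels`, `weights` ((p+1) x K matrix, bias row first),
#'   `feature_names`, `trainer`, and `scaling` (`NULL` unless standardized).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' fit <- linear_classifier(x, rep(c("a", "b"), each = 20))
#' table(predict(fit, x), rep(c("a", "b"), each = 20))
#' @export
linear_classifier <- function(x, labels, method = c("lda", "lsq"),
                              standardize = FALSE, ridge = 1e-8) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("nrow(x) must equal length(labels)")
  if (!all(is.finite(x))) stop("non-finite feature values in training data")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) stop("need at least 2 training samples per class; short: ",
                             paste(classes[counts < 2L], collapse = ", "))
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(x)))

  scaling <- NULL
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }

  solve_reg <- function(a, b) {
    tryCatch(solve(a, b), error = function(e) {
      warning("singular system in training; using ridge-regularized solve")
      lambda <- ridge * mean(diag(a))
      if (!is.finite(lambda) || lambda <= 0) lambda <- ridge
      solve(a + diag(lambda, nrow(a)), b)
    })
  }

  p <- ncol(x)
  if (method == "lda") {
    mus <- t(vapply(classes, function(k) colMeans(x[labels == k, , drop = FALSE]),
                    numeric(p)))
    centered <- x - mus[match(labels, classes), , drop = FALSE]
    s_pool <- crossprod(centered) / (nrow(x) - length(classes))
    wk <- solve_reg(s_pool, t(mus))                       # p x K
    bias <- -0.5 * colSums(t(mus) * wk) + log(as.numeric(counts) / nrow(x))
    weights <- rbind(bias, wk)
  } else {
    y_ind <- outer(labels, classes, "==") * 1
    x1 <- cbind(1, x)
    weights <- solve_reg(crossprod(x1), crossprod(x1, y_ind))
  }
  dimnames(weights) <- list(c("(bias)", feature_names), classes)

  structure(list(class_labels = classes, weights = weights,
                 feature_names = feature_names, trainer = method,
                 scaling = scaling),
            class = "linear_classifier")
}

#' Predict classes or discriminant scores
#'
#' @param object A `linear_classifier`.
#' @param newdata Numeric matrix (rows = items) or a single feature vector,
#'   columns in the model's feature order.
#' @param type `"class"` for labels, `"score"` for the raw discriminant
#'   score matrix.
#' @param ... Unused.
#' @return Character vector of class labels, or a score matrix.
#' @export
predict.linear_classifier <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  p <- length(object$feature_names)
  if (ncol(x) != p)
    stop(sprintf("feature dimension mismatch: model expects %d features, received %d",
                 p, ncol(x)))
  if (!is.null(object$scaling))
    x <- sweep(sweep(x, 2, object$scaling$center), 2, object$scaling$scale, "/")
  scores <- cbind(1, x) %*% object$weights
  if (type == "score") return(scores)
  object$class_labels[max.col(scores, ties.method = "first")]
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf("Linear classifier (%s): %d classes [%s], %d features\n",
              x$trainer, length(x$class_labels),
              paste(x$class_labels, collapse = ", "),
              length(x$feature_names)))
  invisible(x)
}

#' @export
summary.linear_classifier <- function(object, ...) {
  print(object)
  cat("Weight vectors (bias first):\n")
  print(object$weights)
  invisible(object)
}

#' @export
coef.linear_classifier <- function(object, ...) object$weights

#' Confusion matrix of a classifier on a test set
#'
#' @param model A `linear_classifier`.
#' @param test_features Feature matrix, rows = test items.
#' @param test_labels True class label per row.
#' @return An object of class `confusion_matrix`: integer matrix with rows =
#'   true classes and columns = predicted classes, over the model's labels.
#' @export
confusion <- function(model, test_features, test_labels) {
  pred <- predict(model, test_features)
  confusion_matrix_from_labels(test_labels, pred, model$class_labels)
}

#' Build a confusion matrix from true and predicted labels
#'
#' @param true,predicted Label vectors of equal length.
#' @param labels Class label order (defaults to sorted union).
#' @return A `confusion_matrix`.
#' @export
confusion_matrix_from_labels <- function(true, predicted,
                                         labels = sort(unique(c(true, predicted)))) {
  true <- factor(as.character(true), levels = labels)
  predicted <- factor(as.character(predicted), levels = labels)
  m <- unclass(table(true = true, predicted = predicted))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Specificity, per-class sensitivity and accuracy from a confusion matrix
#'
#' Computes the standard event-detection performance measures, all as
#' percentages: specificity = correctly rejected negatives / actual
#' negatives; sensitivity(k) = correctly detected k / actual k for every
#' non-negative class; accuracy = trace / total.
#'
#' @param cm A `confusion_matrix` (or square named count matrix), rows = true
#'   classes.
#' @param negative_class Label of the negative (normal) class.
#' @return List with `specificity`, `sensitivity` (named vector over the
#'   positive classes) and `accuracy`, in percent.
#' @export
metrics_from_confusion <- function(cm, negative_class) {
  m <- as.matrix(unclass(cm))
  labels <- rownames(m)
  if (is.null(labels) || !identical(labels, colnames(m)))
    stop("cm must be a square matrix with matching row/column labels")
  if (!negative_class %in% labels) stop("negative_class not among labels: ", negative_class)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("zero row sum for class: ",
                         paste(labels[rs == 0], collapse = ", "))
  pos <- setdiff(labels, negative_class)
  list(specificity = 100 * m[negative_class, negative_class] / rs[[negative_class]],
       sensitivity = stats::setNames(
         100 * m[cbind(pos, pos)] / rs[pos], pos),
       accuracy = 100 * sum(diag(m)) / sum(m))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Serialize a linear classifier to JSON
#'
#' The layout (class labels, feature names, weight matrix, trainer, scaling
#' statistics) round-trips through [read_model()] with bit-identical
#' predictions.
#'
#' @param model A `linear_classifier`.
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "linear_classifier"))
  payload <- list(format = "eegseize-linear-classifier-v1",
                  trainer = model$trainer,
                  class_labels = model$class_labels,
                  feature_names = model$feature_names,
                  weights = as.vector(model$weights),  # column-major flat
                  scaling = model$scaling)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized linear classifier
#'
#' @param path JSON file written by [write_model()].
#' @return A `linear_classifier`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "eegseize-linear-classifier-v1"))
    stop("not a recognized model file: ", path)
  w <- matrix(as.numeric(p$weights), ncol = length(p$class_labels),
              dimnames = list(c("(bias)", p$feature_names), p$class_labels))
  scaling <- if (!is.null(p$scaling))
    list(center = stats::setNames(as.numeric(p$scaling$center), p$feature_names),
         scale = stats::setNames(as.numeric(p$scaling$scale), p$feature_names))
  structure(list(class_labels = p$class_labels, weights = w,
                 feature_names = p$feature_names, trainer = p$trainer,
                 scaling = scaling),
            class = "linear_classifier")
}
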