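make_clouds <- function(seed, n = 30, p = 4, sep = 10) {
  set.seed(seed)
  centers <- rbind(rep(0, p), c(sep, rep(0, p - 1)), c(0, sep, rep(0, p - 2)))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n * p), n, p), 2, centers[k, ], "+")))
  list(x = x, y = rep(c("0", "1", "2"), each = n), centers = centers)
}

test_that("well-separated clouds are classified perfectly in training", {
  cl <- make_clouds(1)
  fit <- linear_classifier(cl$x, cl$y)
  expect_identical(predict(fit, cl$x), cl$y)
  # class centroids map to their own class
  expect_identical(predict(fit, cl$centers), c("0", "1", "2"))
})

test_that("two duplicated points per class induce the perpendicular bisector", {
  x <- rbind(c(0, 0), c(0, 0), c(4, 0), c(4, 0))
  y <- c("a", "a", "b", "b")
  expect_warning(fit <- linear_classifier(x, y), "ridge")
  probes <- rbind(c(1.9, 5), c(2.1, -3), c(-1, 0), c(5, 1))
  expect_identical(predict(fit, probes), c("a", "b", "a", "b"))
})

test_that("three-class predictions take values only in the label set", {
  cl <- make_clouds(2, sep = 3)
  fit <- linear_classifier(cl$x, cl$y)
  set.seed(3)
  pred <- predict(fit, matrix(rnorm(200 * 4, sd = 5), 200))
  expect_true(all(pred %in% c("0", "1", "2")))
})

test_that("ties break deterministically toward the lowest class index", {
  cl <- make_clouds(4)
  fit <- linear_classifier(cl$x, cl$y)
  fit$weights[] <- 0
  expect_identical(predict(fit, cl$x[1:5, ]), rep("0", 5))
})

test_that("batch prediction equals element-wise single prediction", {
  cl <- make_clouds(5, sep = 2)
  fit <- linear_classifier(cl$x, cl$y)
  batch <- predict(fit, cl$x)
  single <- vapply(seq_len(nrow(cl$x)),
                   function(i) predict(fit, cl$x[i, ]), character(1))
  expect_identical(batch, single)
})

test_that("prediction is invariant to a common shift of all class scores", {
  cl <- make_clouds(6, sep = 2)
  fit <- linear_classifier(cl$x, cl$y)
  shifted <- fit
  shifted$weights["(bias)", ] <- shifted$weights["(bias)", ] + 57.3
  expect_identical(predict(fit, cl$x), predict(shifted, cl$x))
})

test_that("dimension mismatches and bad training sets are rejected", {
  cl <- make_clouds(7)
  fit <- linear_classifier(cl$x, cl$y)
  expect_error(predict(fit, matrix(0, 2, 7)), "expects 4 features, received 7")
  expect_error(linear_classifier(cl$x, rep("z", nrow(cl$x))), "2 classes")
  expect_error(linear_classifier(cl$x[1:31, ], c(rep("a", 30), "b")),
               "2 training samples per class")
  xx <- cl$x; xx[1, 1] <- NA
  expect_error(linear_classifier(xx, cl$y), "non-finite")
})

test_that("pooled-covariance discriminants agree with the classical reference", {
  skip_if_not_installed("MASS")
  cl <- make_clouds(8, sep = 2.5)
  fit <- linear_classifier(cl$x, cl$y)
  ref <- MASS::lda(cl$x, grouping = cl$y)
  set.seed(9)
  probes <- matrix(rnorm(300 * 4, sd = 4), 300)
  expect_identical(predict(fit, probes),
                   as.character(predict(ref, probes)$class))
})

test_that("confusion matrices count true class by predicted class", {
  cl <- make_clouds(10)
  fit <- linear_classifier(cl$x, cl$y)
  cm <- confusion(fit, cl$x, cl$y)
  expect_true(all(cm == diag(c(30, 30, 30))))       # perfect classifier
  expect_identical(unname(rowSums(cm)), rep(30, 3)) # conservation
  # constant classifier: one nonzero column
  fit0 <- fit
  fit0$weights[] <- 0
  cm0 <- confusion(fit0, cl$x, cl$y)
  expect_identical(unname(colSums(cm0 > 0) > 0), c(TRUE, FALSE, FALSE))
})

test_that("metrics from the published 3-class confusion matrix are reproduced", {
  cm <- matrix(c(514, 86, 0,
                 135, 456, 9,
                 9, 45, 546), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "D", "E"), c("A", "D", "E")))
  m <- metrics_from_confusion(cm, negative_class = "A")
  expect_equal(m$specificity, 100 * 514 / 600)
  expect_equal(floor(m$specificity * 10) / 10, 85.6)
  expect_equal(m$sensitivity[["D"]], 76)
  expect_equal(m$sensitivity[["E"]], 91)
  expect_equal(round(m$accuracy, 1), 84.2)
})

test_that("metric edge cases behave: identity matrix, zero rows, bounds", {
  id <- diag(5L, 3)
  dimnames(id) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- metrics_from_confusion(id, "a")
  expect_equal(m$accuracy, 100)
  expect_equal(m$specificity, 100)
  expect_true(all(m$sensitivity == 100))
  zd <- id; diag(zd) <- 0; zd[1, 2] <- 5; zd[2, 3] <- 5; zd[3, 1] <- 5
  expect_equal(metrics_from_confusion(zd, "a")$accuracy, 0)
  bad <- id; bad[2, ] <- 0
  expect_error(metrics_from_confusion(bad, "a"), "zero row sum")
})

test_that("models round-trip through JSON with bit-identical predictions", {
  cl <- make_clouds(11, sep = 1.5)
  fit <- linear_classifier(cl$x, cl$y, standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(back, cl$x, type = "score"),
                   predict(fit, cl$x, type = "score"))
  expect_identical(predict(back, cl$x), predict(fit, cl$x))
})

test_that("the least-squares trainer also separates easy classes", {
  cl <- make_clouds(12)
  fit <- linear_classifier(cl$x, cl$y, method = "lsq")
  expect_identical(fit$trainer, "lsq")
  expect_identical(predict(fit, cl$x), cl$y)
})
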