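# Task-classifier construction, prediction contract, training and the
# confusion-matrix evaluation.

small_cfg <- function(K = 2L, ...) {
  classifier_config(conv_blocks = list(c(4L, 3L, 2L), c(8L, 3L, 2L)),
                    fc_widths = c(16L), K = K, ...)
}

test_that("building is deterministic and outputs are probability vectors", {
  ds <- tiny_dataset()
  cfg <- small_cfg(seed = 13L)
  a <- build_classifier(cfg, c(8L, 16L))
  b <- build_classifier(cfg, c(8L, 16L))
  pa <- predict(a, ds$maps[1:3])
  pb <- predict(b, ds$maps[1:3])
  expect_identical(pa$probs, pb$probs)
  expect_true(all(pa$probs >= 0))
  expect_equal(colSums(pa$probs), rep(1, 3), tolerance = 1e-6)
})

test_that("an untrained 7-class net scores near ln 7 crossentropy", {
  ds <- generate_synthetic_dataset(synth_config(H = 16L, W = 16L, K = 7L,
                                                n_per_class = 2L, seed = 3L))
  clf <- build_classifier(small_cfg(K = 7L, seed = 1L), c(16L, 16L))
  ce <- cagen:::clf_ce_and_acc(clf, ds$maps, cagen:::ds_labels(ds))$loss
  expect_lt(abs(ce - log(7)), 0.5)
})

test_that("argmax assignment breaks ties toward the lowest class", {
  expect_equal(assign_class(c(0.9, 0.1)), 0L)
  expect_equal(assign_class(c(0.5, 0.5)), 0L)
  expect_equal(assign_class(c(0.1, 0.45, 0.45)), 1L)
  p <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)
  expect_equal(assign_class(p), c(1L, 0L))
})

test_that("batch prediction equals per-map prediction", {
  ds <- tiny_dataset()
  clf <- build_classifier(small_cfg(seed = 2L), c(8L, 16L))
  batch <- predict(clf, ds)
  single <- vapply(ds$maps, function(m) predict(clf, m)$class, integer(1))
  expect_equal(batch$class, single)
  expect_error(predict(clf, activation_map(matrix(0.5, 4, 4), matrix(TRUE, 4, 4))),
               "does not match")
})

test_that("training overfits a small sample and rejects bad input", {
  ds <- tiny_dataset(n_per_class = 5L, noise_sd = 0.08)
  cfg <- small_cfg(lr = 0.08, epochs = 25L, folds = 0L, seed = 5L)
  clf <- build_classifier(cfg, c(8L, 16L))
  fit <- train_classifier(clf, ds, cfg)
  expect_equal(cagen:::clf_ce_and_acc(fit$classifier, ds$maps,
                                      cagen:::ds_labels(ds))$acc, 1)
  expect_true(all(is.finite(fit$history$loss)))

  expect_error(train_classifier(clf, labeled_dataset(list(), ds$class_names)),
               "empty")
  labs <- cagen:::ds_labels(ds)
  one <- labeled_dataset(ds$maps[labs == 0], ds$class_names)
  expect_error(train_classifier(clf, one, cfg), "single-class")
})

test_that("stratified folds partition the data and balance classes", {
  labels <- rep(0:2, times = c(20, 23, 17))
  fold <- stratified_folds(labels, 10L, seed = 3L)
  expect_setequal(unique(fold), 1:10)
  expect_equal(sort(unlist(lapply(1:10, function(f) which(fold == f)))),
               seq_along(labels))
  for (k in 0:2) {
    per <- table(fold[labels == k])
    expect_lte(max(per) - min(per), 1)
  }
})

test_that("crossvalidated training reports per-fold histories", {
  ds <- tiny_dataset(n_per_class = 6L)
  cfg <- small_cfg(lr = 0.08, epochs = 2L, folds = 3L, seed = 5L)
  fit <- train_classifier(build_classifier(cfg, c(8L, 16L)), ds, cfg)
  expect_setequal(unique(fit$history$fold), 0:3)
  cv <- fit$history[fit$history$fold > 0, ]
  expect_true(all(is.finite(cv$val_acc)))
})

test_that("confusion matrices count true-by-assigned and report accuracy", {
  ds <- tiny_dataset(K = 3L, n_per_class = 4L)
  labs <- cagen:::ds_labels(ds)
  perfect <- function(maps) labs
  cm <- evaluate_confusion(perfect, ds)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(unname(diag(cm)), as.vector(table(labs)))
  expect_equal(attr(cm, "accuracy"), 1)
  expect_equal(unname(rowSums(cm)), as.vector(table(labs)))

  unl <- ds
  unl$maps[[1]]$label <- NA_integer_
  expect_error(evaluate_confusion(perfect, unl), "unlabeled")
})

test_that("a uniform random predictor scores at chance on K = 7", {
  K <- 7L; n <- 7000L
  maps <- rep(list(activation_map(matrix(0.5, 2, 2), matrix(TRUE, 2, 2),
                                  label = 0L)), n)
  labs <- rep_len(0:(K - 1L), n)
  for (i in seq_len(n)) maps[[i]]$label <- labs[i]
  ds <- labeled_dataset(maps, paste0("c", 1:K))
  set.seed(123)
  rand <- function(maps) sample.int(K, length(maps), replace = TRUE) - 1L
  cm <- evaluate_confusion(rand, ds)
  acc <- attr(cm, "accuracy")
  sd3 <- 3 * sqrt((1 / K) * (1 - 1 / K) / n)
  expect_lt(abs(acc - 1 / K), sd3)
})

test_that("classifier checkpoints restore predictions bit-exactly", {
  ds <- tiny_dataset()
  clf <- build_classifier(small_cfg(seed = 8L), c(8L, 16L))
  f <- tempfile(fileext = ".ckpt")
  save_classifier(clf, f)
  back <- load_classifier(f)
  expect_identical(predict(back, ds)$probs, predict(clf, ds)$probs)
})
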