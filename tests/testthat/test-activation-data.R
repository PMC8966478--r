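# Data model, synthetic generator, preprocessing and container round-trips.

test_that("activation maps enforce mask zeroing and shape agreement", {
  v <- matrix(runif(12), 3, 4)
  msk <- matrix(c(TRUE, FALSE), 3, 4)
  m <- activation_map(v, msk)
  expect_true(all(m$values[!msk] == 0))
  expect_error(activation_map(v, matrix(TRUE, 2, 2)))
  expect_error(activation_map(matrix(c(1, NA, 1, 1), 2, 2), matrix(TRUE, 2, 2)))
})

test_that("synthetic generator handles the empty and noise-free limits", {
  empty <- generate_synthetic_dataset(synth_config(H = 12L, W = 16L, K = 3L,
                                                   n_per_class = 0L, seed = 1L))
  expect_length(empty$maps, 0)
  expect_length(empty$class_names, 3)

  nf <- generate_synthetic_dataset(synth_config(H = 12L, W = 16L, K = 2L,
                                                n_per_class = 3L, noise_sd = 0,
                                                blob_width = 1.5, seed = 4L))
  labs <- cagen:::ds_labels(nf)
  for (k in 0:1) {
    grp <- nf$maps[labs == k]
    for (m in grp[-1]) expect_identical(m$values, grp[[1]]$values)
  }
})

test_that("synthetic datasets are reproducible and structured", {
  cfg <- synth_config(H = 16L, W = 24L, K = 3L, n_per_class = 4L, seed = 9L)
  a <- generate_synthetic_dataset(cfg)
  b <- generate_synthetic_dataset(cfg)
  expect_identical(lapply(a$maps, `[[`, "values"), lapply(b$maps, `[[`, "values"))

  msk <- cagen:::ds_mask(a)
  for (m in a$maps) {
    expect_true(all(m$values[!msk] == 0))
    expect_true(all(m$values >= 0 & m$values <= 1))
    expect_equal(range(m$values[msk]), c(0, 1))
  }
  cm <- class_means(a)
  d <- combn(3, 2, function(p) sqrt(sum((cm[[p[1]]] - cm[[p[2]]])^2)))
  expect_true(min(d) > 0)
  expect_error(generate_synthetic_dataset(cfg, mask = matrix(FALSE, 16, 24)),
               "degenerate mask")
})

test_that("a nearest-class-mean rule classifies fresh synthetic samples perfectly", {
  full <- generate_synthetic_dataset(synth_config(H = 16L, W = 32L, K = 4L,
                                                  n_per_class = 8L, seed = 5L))
  sp <- split_dataset(full, 3L, seed = 2L)
  clf <- nearest_mean_clf(sp$train)
  pred <- clf(sp$holdout$maps)
  expect_equal(pred, cagen:::ds_labels(sp$holdout))
})

test_that("downsampling is exact area-weighted averaging", {
  msk <- matrix(TRUE, 4, 4)
  cst <- activation_map(matrix(0.37, 4, 4), msk)
  expect_equal(downsample(cst, 3, 2)$values, matrix(0.37, 3, 2))
  ones <- activation_map(matrix(1, 4, 4), msk)
  expect_equal(downsample(ones, 2, 2)$values, matrix(1, 2, 2))
  checker <- activation_map(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2))
  expect_equal(downsample(checker, 1, 1)$values, matrix(0.5, 1, 1))

  set.seed(6)
  for (rep in 1:4) {
    H <- sample(6:14, 1); W <- sample(6:14, 1)
    th <- sample(2:H, 1); tw <- sample(2:W, 1)
    m <- activation_map(matrix(runif(H * W), H, W), matrix(TRUE, H, W))
    expect_equal(mean(downsample(m, th, tw)$values), mean(m$values),
                 tolerance = 1e-12)
  }
  expect_error(downsample(cst, 0, 2))
  expect_error(downsample(cst, 5, 2))
})

test_that("downsampled masks follow the majority vote and are re-applied", {
  v <- matrix(1, 4, 4)
  msk <- matrix(FALSE, 4, 4)
  msk[1:3, 1:2] <- TRUE              # left 2x2 block mostly inside
  m <- downsample(activation_map(v, msk), 2, 2)
  expect_identical(m$mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_true(all(m$values[!m$mask] == 0))
})

test_that("min-max normalization rescales within the mask only", {
  msk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  m <- activation_map(matrix(c(2, 4, 6, 0), 2, 2), msk)
  nz <- minmax_normalize(m)
  expect_equal(nz$values[msk], c(0, 0.5, 1))
  expect_equal(nz$values[!msk], 0)

  spanning <- activation_map(matrix(c(0, 0.25, 1, 0), 2, 2), msk)
  expect_identical(minmax_normalize(spanning)$values, spanning$values)

  flat <- activation_map(matrix(c(3, 3, 3, 0), 2, 2) * (msk + 0), msk)
  expect_error(minmax_normalize(flat), "degenerate")
})

test_that("the dataset container round-trips bit-exactly", {
  ds <- tiny_dataset(n_per_class = 3L)
  f <- tempfile(fileext = ".cagd")
  save_dataset(ds, f)
  back <- load_dataset(f)
  expect_identical(lapply(back$maps, `[[`, "values"),
                   lapply(ds$maps, `[[`, "values"))
  expect_identical(cagen:::ds_labels(back), cagen:::ds_labels(ds))
  expect_identical(back$class_names, ds$class_names)
  expect_identical(cagen:::ds_mask(back), cagen:::ds_mask(ds))

  e <- labeled_dataset(list(), c("a", "b"))
  f2 <- tempfile(fileext = ".cagd")
  save_dataset(e, f2)
  expect_length(load_dataset(f2)$maps, 0)
  expect_error(load_dataset(tempfile()), "not found")
})

test_that("PNG export quantizes linearly to 8-bit gray", {
  msk <- matrix(TRUE, 2, 2)
  m <- activation_map(matrix(c(0, 1, 0.5, 1), 2, 2), msk)
  f <- tempfile(fileext = ".png")
  export_png(m, f)
  img <- png::readPNG(f)
  expect_equal(img * 255, round(m$values * 255), tolerance = 1e-9)
  expect_equal(sort(unique(as.vector(img * 255))), c(0, 128, 255))
})
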