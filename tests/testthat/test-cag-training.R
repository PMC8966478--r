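# Loss operations against analytic values and direct formula recomputation;
# step functions against the parameter-partition contract; small training
# runs for the optimization behavior.

test_that("Wasserstein terms are mean score differences", {
  ds <- tiny_dataset()
  const_critic <- function(maps) rep(1.7, length(maps))
  w <- wasserstein_terms(const_critic, ds$maps[1:3], ds$maps[4:6])
  expect_equal(w$lwass, 0)

  # a critic that scores each map by a lookup on its id
  lookup_critic <- function(tbl) function(maps)
    unname(tbl[vapply(maps, `[[`, character(1), "id")])
  tbl <- c(2.0, 0.5, 1, 3, 0, 2)
  names(tbl) <- vapply(ds$maps[1:6], `[[`, character(1), "id")
  crit <- lookup_critic(tbl)
  w1 <- wasserstein_terms(crit, ds$maps[1], ds$maps[2])
  expect_equal(w1$lwass_r, 2.0)
  expect_equal(w1$lwass_f, 0.5)
  expect_equal(w1$lwass, 1.5)
  w2 <- wasserstein_terms(crit, ds$maps[3:4], ds$maps[5:6])
  expect_equal(w2$lwass, 2 - 1)
  expect_error(wasserstein_terms(const_critic, list(), ds$maps[1:2]), "empty")
})

test_that("gradient penalty is exact for linear critics", {
  ds <- tiny_dataset(H = 6L, W = 8L, noise_sd = 0.1)
  D <- 6L * 8L
  w_unit <- rnorm(D); w_unit <- w_unit / sqrt(sum(w_unit^2))
  expect_equal(gradient_penalty(linear_critic(w_unit), ds$maps[1:4], ds$maps[5:8]),
               0, tolerance = 1e-10)
  w3 <- w_unit * 3
  set.seed(2)
  expect_equal(gradient_penalty(linear_critic(w3), ds$maps[1:4], ds$maps[5:8]),
               4, tolerance = 1e-8)
  # independence of the interpolation point for linear critics
  a <- gradient_penalty(linear_critic(w3), ds$maps[1:4], ds$maps[5:8],
                        t = rep(0.2, 4))
  b <- gradient_penalty(linear_critic(w3), ds$maps[1:4], ds$maps[5:8],
                        t = rep(0.9, 4))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the critic input gradient matches central finite differences", {
  set.seed(31)
  ds <- tiny_dataset(H = 8L, W = 8L)
  disc <- build_discriminator(2L, 8L, 8L, base_ch = 4L, seed = 6L)
  arr <- cagen:::maps_to_array(ds$maps[1])
  x <- cagen:::ad_leaf(arr)
  src <- cagen:::disc_src_node(disc, cagen:::params_as_consts(disc$par), x, 1L)
  g <- cagen:::ad_value(cagen:::ad_grad(cagen:::ad_sum(src), list(x))[[1]])
  pick <- sample(length(arr), 8)
  fd <- vapply(pick, function(i) {
    e <- 1e-5
    ap <- arr; am <- arr; ap[i] <- ap[i] + e; am[i] <- am[i] - e
    score <- function(a) as.numeric(cagen:::ad_value(cagen:::disc_src_node(
      disc, cagen:::params_as_consts(disc$par), cagen:::ad_const(a), 1L)))
    (score(ap) - score(am)) / (2 * e)
  }, numeric(1))
  denom <- pmax(abs(fd), 1e-3)
  expect_lt(max(abs(g[pick] - fd) / denom), 1e-4)
})

test_that("domain and guidance losses hit the analytic crossentropy values", {
  ds <- tiny_dataset(K = 2L)
  maps <- ds$maps[1:4]
  K7 <- make_const_prob_clf(rep(1 / 7, 7))
  onehot <- make_const_prob_clf(c(1, 0, 0))
  half <- make_const_prob_clf(c(0.5, 0.3, 0.2))
  quarter <- make_const_prob_clf(c(0.25, 0.5, 0.25))

  expect_equal(domain_loss_real(onehot, maps, rep(0L, 4)), 0, tolerance = 1e-9)
  expect_equal(domain_loss_real(K7, maps, rep(3L, 4)), log(7), tolerance = 1e-9)
  expect_equal(domain_loss_real(half, maps, rep(0L, 4)), log(2), tolerance = 1e-9)

  expect_equal(classifier_guidance_loss(onehot, maps, rep(0L, 4)), 0,
               tolerance = 1e-9)
  expect_equal(classifier_guidance_loss(K7, maps, rep(1L, 4)), log(7),
               tolerance = 1e-9)
  expect_equal(classifier_guidance_loss(quarter, maps, rep(0L, 4)), log(4),
               tolerance = 1e-9)

  # fake-domain loss equals the real-domain loss evaluated on the fakes
  wg <- make_wiggle_gen(0.1)
  targets <- c(0L, 1L, 0L, 1L)
  fakes <- wg(maps, targets)
  expect_equal(domain_loss_fake(half, wg, maps, targets),
               domain_loss_real(half, fakes, targets), tolerance = 1e-12)
})

test_that("reconstruction loss equals the masked L1 formula", {
  ds <- tiny_dataset()
  maps <- ds$maps[1:4]
  labs <- vapply(maps, `[[`, integer(1), "label")
  targets <- 1L - labs
  expect_equal(reconstruction_loss(identity_gen, maps, targets), 0)

  # a generator that adds delta per pass moves the map by 2*delta after a cycle
  delta <- 0.013
  expect_equal(reconstruction_loss(make_delta_gen(delta), maps, targets),
               2 * delta, tolerance = 1e-12)

  # direct recomputation oracle for an arbitrary toy generator
  wg <- make_wiggle_gen(0.07)
  got <- reconstruction_loss(wg, maps, targets)
  msk <- maps[[1]]$mask
  once <- wg(maps, targets)
  twice <- wg(once, labs)
  oracle <- mean(vapply(seq_along(maps), function(i)
    mean(abs(maps[[i]]$values[msk] - twice[[i]]$values[msk])), numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-9)
})

make_train_state <- function(K = 2L, H = 8L, W = 16L, seed = 17L,
                             weights = loss_weights(), batch_size = 4L,
                             lr = 5e-4) {
  ds <- tiny_dataset(H = H, W = W, K = K, n_per_class = 4L, seed = seed)
  clf <- build_classifier(
    classifier_config(conv_blocks = list(c(4L, 3L, 2L), c(8L, 3L, 2L)),
                      fc_widths = c(16L), K = K, seed = seed), c(H, W))
  cfg <- cag_train_config(batch_size = batch_size, lr = lr,
                          gen_base_ch = 4L, disc_base_ch = 4L, seed = seed)
  set.seed(seed)
  list(st = cag_init_state(clf, ds, weights, cfg), ds = ds, clf = clf)
}

test_that("each training step updates exactly its own network", {
  s <- make_train_state()
  st <- s$st
  gen0 <- st$gen$par; disc0 <- st$disc$par; clf0 <- st$clf$par
  rep_d <- discriminator_step(st)
  expect_identical(st$gen$par, gen0)
  expect_identical(st$clf$par, clf0)
  expect_false(identical(st$disc$par, disc0))
  expect_true(all(vapply(rep_d, is.finite, logical(1))))

  disc1 <- st$disc$par
  rep_g <- generator_step(st)
  expect_identical(st$disc$par, disc1)
  expect_identical(st$clf$par, clf0)
  expect_false(identical(st$gen$par, gen0))
  expect_true(all(vapply(rep_g, is.finite, logical(1))))
})

test_that("step reports agree with the standalone loss operations", {
  s <- make_train_state()
  st <- s$st
  batch <- cagen:::sample_batch(st)
  disc_before <- st$disc
  rep_d <- discriminator_step(st, batch)
  maps <- cagen:::array_to_maps(batch$arr, st$mask)
  expect_equal(rep_d$lcls_r,
               domain_loss_real(disc_before, maps, batch$labels),
               tolerance = 1e-9)
  w <- wasserstein_terms(disc_before, maps,
                         cagen:::cag_translate(st$gen, maps, batch$targets))
  expect_equal(rep_d$lwass_r, w$lwass_r, tolerance = 1e-9)
  expect_equal(rep_d$lwass_f, w$lwass_f, tolerance = 1e-9)
})

test_that("critic steps widen the real-fake score gap", {
  s <- make_train_state(weights = loss_weights(lambda_gp = 0, lambda_cls = 0),
                        lr = 2e-3)
  st <- s$st
  batch <- cagen:::sample_batch(st)
  gap <- function() {
    r <- discriminate(st$disc, cagen:::array_to_maps(batch$arr, st$mask))$realness
    fake <- cagen:::gen_translate_array(st$gen, batch$arr, batch$targets, st$mask)
    f <- discriminate(st$disc, cagen:::array_to_maps(fake, st$mask))$realness
    mean(r) - mean(f)
  }
  g0 <- gap()
  for (i in 1:10) discriminator_step(st, batch)
  expect_gt(gap(), g0)
})

test_that("generator steps reduce the reconstruction loss on a fixed batch", {
  s <- make_train_state(weights = loss_weights(lambda_gp = 0, lambda_cls = 0,
                                               lambda_rec = 10, lambda_cnn = 0),
                        lr = 2e-3)
  st <- s$st
  batch <- cagen:::sample_batch(st)
  r0 <- generator_step(st, batch)$lrec
  for (i in 1:49) rep_g <- generator_step(st, batch)
  expect_lt(rep_g$lrec, r0)
})

test_that("training runs, records finite losses, and is seed-reproducible", {
  run <- function() {
    s <- make_train_state()
    cfg <- cag_train_config(batch_size = 4L, lr = 5e-4, gen_steps = 6L,
                            gen_base_ch = 4L, disc_base_ch = 4L, seed = 23L)
    train_cag(s$clf, s$ds, loss_weights(), cfg)
  }
  a <- run()
  expect_equal(nrow(a$history), 6)
  expect_true(all(is.finite(as.matrix(a$history))))
  expect_false(a$diverged)
  b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$gen$par, b$gen$par)
})

test_that("lambda_cnn = 0 reduces to the plain two-domain adversarial setup", {
  s <- make_train_state(weights = loss_weights(lambda_cnn = 0))
  cfg <- cag_train_config(batch_size = 4L, lr = 5e-4, gen_steps = 3L,
                          gen_base_ch = 4L, disc_base_ch = 4L, seed = 29L)
  res <- train_cag(s$clf, s$ds, loss_weights(lambda_cnn = 0), cfg)
  expect_equal(nrow(res$history), 3)
  # the guidance term is still computed and reported, just unweighted
  expect_true(all(is.finite(res$history$lcnn)))
})
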