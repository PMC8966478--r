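# CE construction identities, percentile thresholding against a brute-force
# oracle, the perturbation sweep, and the delta-average/kappa control.

test_that("explanations satisfy the additivity identity exactly", {
  ds <- tiny_dataset()
  m <- ds$maps[[1]]
  wg <- make_wiggle_gen(0.1)
  ex <- explain(wg, NULL, m, target = 1L - m$label)
  expect_identical(ex$original$values + ex$ce, ex$counterfactual$values)
  expect_true(all(ex$ce[!m$mask] == 0))

  idex <- explain(identity_gen, NULL, m, target = 1L - m$label)
  expect_true(all(idex$ce == 0))
  expect_error(explain(wg, NULL, m, target = m$label), "target class equals")
})

# Independent percentile oracle: sort-based linear interpolation between
# order statistics, then zero strictly-below pixels.
oracle_threshold <- function(ce, alpha, mask, ranking = "absolute") {
  out <- ce; out[!mask] <- 0
  if (alpha == 0) return(out)
  if (alpha == 100) { out[] <- 0; return(out) }
  stat <- if (ranking == "absolute") abs(ce) else ce
  v <- sort(stat[mask])
  h <- (length(v) - 1) * alpha / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  thr <- v[lo] + (h - lo) * (v[hi] - v[lo])
  out[mask & stat < thr] <- 0
  out
}

test_that("threshold_ce matches the brute-force percentile oracle", {
  set.seed(44)
  for (rep in 1:6) {
    ce <- matrix(rnorm(50), 5, 10)
    mask <- matrix(runif(50) < 0.8, 5, 10)
    if (!any(mask)) mask[1] <- TRUE
    for (alpha in c(0, 13, 20, 40, 55, 60, 80, 99, 100)) {
      for (rk in c("absolute", "signed")) {
        expect_equal(threshold_ce(ce, alpha, mask, rk),
                     oracle_threshold(ce, alpha, mask, rk))
      }
    }
  }
  expect_error(threshold_ce(matrix(1, 2, 2), -5), "alpha")
  expect_error(threshold_ce(matrix(1, 2, 2), 101), "alpha")
})

test_that("a known magnitude set zeroes exactly the two smallest pixels at alpha 40", {
  ce <- matrix(c(0.5, -1, 2, -3, 4), 1, 5)
  out <- threshold_ce(ce, 40, matrix(TRUE, 1, 5), "absolute")
  expect_equal(out, matrix(c(0, 0, 2, -3, 4), 1, 5))
})

test_that("thresholding zeroes a nested, growing set of pixels as alpha grows", {
  set.seed(9)
  ce <- matrix(rnorm(60), 6, 10)
  mask <- matrix(TRUE, 6, 10)
  alphas <- seq(0, 100, by = 10)
  prev <- threshold_ce(ce, 0, mask)
  for (a in alphas[-1]) {
    cur <- threshold_ce(ce, a, mask)
    expect_true(all(cur[prev == 0] == 0))   # support shrinks monotonically
    prev <- cur
  }
})

test_that("alpha = 0 and alpha = 100 reconstruct counterfactual and original", {
  ds <- tiny_dataset()
  m <- ds$maps[[3]]
  ex <- explain(make_wiggle_gen(0.15), NULL, m, target = 1L - m$label)
  ce0 <- threshold_ce(ex$ce, 0, m$mask)
  expect_identical(m$values + ce0, ex$counterfactual$values)
  ce100 <- threshold_ce(ex$ce, 100, m$mask)
  expect_identical(m$values + ce100, m$values)
})

test_that("delta-average controls are class-mean differences", {
  ds <- tiny_dataset(K = 3L, n_per_class = 3L)
  expect_true(all(control_delta_ave(ds, 1L, 1L) == 0))

  one_each <- labeled_dataset(ds$maps[c(1, 4)], ds$class_names)
  d <- control_delta_ave(one_each, 0L, 1L)
  expect_equal(d, (ds$maps[[4]]$values - ds$maps[[1]]$values) *
                 (cagen:::ds_mask(ds) + 0))

  doubled <- labeled_dataset(c(ds$maps, ds$maps), ds$class_names)
  expect_equal(control_delta_ave(doubled, 0L, 2L),
               control_delta_ave(ds, 0L, 2L))
})

test_that("kappa search equals brute-force grid maximization", {
  ds <- tiny_dataset(n_per_class = 4L, noise_sd = 0.05)
  labs <- cagen:::ds_labels(ds)
  cases <- lapply(which(labs == 0L), function(i)
    explain(make_wiggle_gen(0.1), NULL, ds$maps[[i]], target = 1L))
  dav <- control_delta_ave(ds, 0L, 1L)
  nmc <- nearest_mean_clf(ds)
  ks <- kappa_search(nmc, cases, dav)
  # independent brute force over the printed grid
  grid <- seq(0, 5, by = 0.1)
  brute <- vapply(grid, function(kp) {
    sum(vapply(cases, function(cs) {
      v <- cagen:::normalize_matrix(cs$original$values + kp * dav,
                                    cs$original$mask)
      nmc(list(activation_map(v, cs$original$mask))) == cs$target_class
    }, logical(1)))
  }, numeric(1))
  expect_equal(ks$count, max(brute))
  expect_equal(ks$kappa, grid[which.max(brute)])
  expect_equal(ks$counts, as.integer(brute))
})

test_that("a constructed decision threshold is recovered exactly by kappa search", {
  msk <- matrix(TRUE, 4, 4)
  base <- matrix(seq(0, 1, length.out = 16), 4, 4)
  orig <- activation_map(base, msk, label = 0L)
  dav <- matrix(0, 4, 4); dav[1, 1] <- 1
  # after normalization the brightest untouched pixel shrinks monotonically
  # as kappa raises the maximum; the toy flips to class 1 exactly when it
  # drops to its value at kappa = 1.3
  cutoff <- cagen:::normalize_matrix(base + 1.3 * dav, msk)[4, 4] + 1e-9
  toy <- function(maps) vapply(maps, function(m)
    as.integer(m$values[4, 4] <= cutoff), integer(1))
  case <- structure(list(original = orig, counterfactual = orig,
                         ce = matrix(0, 4, 4), source_class = 0L,
                         target_class = 1L),
                    class = "counterfactual_explanation")
  ks <- kappa_search(toy, list(case), dav)
  expect_equal(ks$kappa, 1.3)
  expect_equal(ks$count, 1L)
})

test_that("kappa = 0 reproduces the original classifications", {
  ds <- tiny_dataset(n_per_class = 3L)
  labs <- cagen:::ds_labels(ds)
  nmc <- nearest_mean_clf(ds)
  cases <- lapply(which(labs == 0L), function(i)
    explain(make_wiggle_gen(0.1), NULL, ds$maps[[i]], target = 1L))
  dav <- control_delta_ave(ds, 0L, 1L)
  ks <- kappa_search(nmc, cases, dav, grid = 0)
  orig_cls <- nmc(lapply(cases, function(cs) cs$original))
  expect_equal(ks$count, sum(orig_cls == 1L))
})

test_that("the perturbation sweep counts target assignments per alpha", {
  ds <- tiny_dataset(n_per_class = 5L, noise_sd = 0.05)
  labs <- cagen:::ds_labels(ds)
  nmc <- nearest_mean_clf(ds)
  # correct-case protocol: cases are correctly classified, target != source
  correct <- which(nmc(ds$maps) == labs)
  # toy generator that morphs strongly toward the target class mean
  cm <- class_means(ds)
  toward <- function(maps, targets) {
    targets <- rep_len(targets, length(maps))
    lapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      v <- 0.3 * m$values + 0.7 * cm[[targets[i] + 1L]]
      activation_map(pmin(pmax(v, 0), 1) * m$mask, m$mask, label = m$label,
                     id = m$id)
    })
  }
  cases <- lapply(correct, function(i)
    explain(toward, NULL, ds$maps[[i]], target = 1L - labs[i]))
  sw <- perturbation_sweep(nmc, cases)
  expect_equal(sw$alpha, seq(0, 100, by = 20))
  expect_true(all(sw$count >= 0 & sw$count <= length(cases)))
  # alpha = 100 reduces to the originals, which are assigned source != target
  expect_equal(sw$count[sw$alpha == 100], 0)
  # alpha = 0 equals counting classifier hits on normalized counterfactuals
  hits0 <- sum(vapply(cases, function(cs)
    nmc(list(minmax_normalize(cs$counterfactual))) == cs$target_class,
    logical(1)))
  expect_equal(sw$count[sw$alpha == 0], hits0)
  expect_error(perturbation_sweep(nmc, list()), "empty")
})
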