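# Counterfactual exaggeration: iterated re-translation of one map toward one
# class amplifies the image features that drive the classifier toward that
# class; differencing two iterations isolates them as a texture-like feature
# map whose injection into other maps biases the classifier.

#' Iteratively exaggerate a map toward a target class
#'
#' Applies the generator `n` times, feeding each output back in with the same
#' target class.  `maps[[1]]` is the original; `maps[[i+1]]` is iteration i.
#'
#' @param gen A `cag_generator` (or toy function `(maps, targets) -> maps`).
#' @param map The starting [activation_map].
#' @param target 0-based target class.
#' @param n Number of iterations (>= 1, default 8).
#' @return An `exaggeration_trajectory` with fields `maps` (length n+1),
#'   `target_class`, `source_id`.
#' @export
exaggerate <- function(gen, map, target, n = 8L) {
  stopifnot(inherits(map, "activation_map"))
  if (n < 1L) stop("n must be at least 1")
  maps <- vector("list", n + 1L)
  maps[[1L]] <- map
  cur <- map
  for (i in seq_len(n)) {
    cur <- if (is.function(gen)) gen(list(cur), target)[[1L]]
           else generate_counterfactual(gen, cur, target)
    maps[[i + 1L]] <- cur
  }
  structure(list(maps = maps, target_class = as.integer(target),
                 source_id = map$id),
            class = "exaggeration_trajectory")
}

#' Extract the exaggerated texture feature from a trajectory
#'
#' The feature is the pixelwise difference between a late and an earlier
#' iteration (defaults: iteration 8 minus iteration 3), which cancels the
#' shared image content and keeps what the repeated translation keeps
#' amplifying.
#'
#' @param traj An `exaggeration_trajectory` with at least `iter_late`
#'   iterations.
#' @param iter_late,iter_early Iteration indices used for the difference.
#' @return An `extracted_feature` with fields `feature` (matrix, zero outside
#'   the mask), `target_class`, `source_id`, `iterations`.
#' @export
extract_feature <- function(traj, iter_late = 8L, iter_early = 3L) {
  stopifnot(inherits(traj, "exaggeration_trajectory"))
  if (length(traj$maps) < iter_late + 1L)
    stop("trajectory too short: needs at least ", iter_late, " iterations")
  f <- traj$maps[[iter_late + 1L]]$values - traj$maps[[iter_early + 1L]]$values
  f[!traj$maps[[1L]]$mask] <- 0
  structure(list(feature = f, target_class = traj$target_class,
                 source_id = traj$source_id,
                 iterations = c(iter_early, iter_late)),
            class = "extracted_feature")
}

#' Inject a feature into every map of a dataset and measure the bias
#'
#' Adds the feature to each activation (no renormalization; values are
#' clipped to \[0, 1\] to respect the classifier input range) and returns the
#' fraction of maps the classifier assigns to the feature's target class.
#'
#' @param clf The `task_classifier`.
#' @param feature An `extracted_feature` (or bare numeric matrix plus
#'   `target` argument).
#' @param ds A nonempty [labeled_dataset].
#' @param target Target class when `feature` is a bare matrix.
#' @return Fraction in \[0, 1\].
#' @export
inject_and_evaluate <- function(clf, feature, ds, target = NULL) {
  if (inherits(feature, "extracted_feature")) {
    target <- feature$target_class
    feature <- feature$feature
  }
  stopifnot(!is.null(target), length(ds$maps) > 0)
  mask <- ds_mask(ds)
  injected <- lapply(ds$maps, function(m) {
    v <- pmin(pmax(m$values + feature, 0), 1)
    v[!mask] <- 0
    activation_map(v, mask)
  })
  mean(clf_assign_maps(clf, injected) == target)
}

#' Feature battery: extracted-feature injection against chance
#'
#' Samples `n_features` source maps (seeded), draws a random target class per
#' feature (uniform over the classes other than the source map's), runs the
#' exaggeration-extraction-injection pipeline for each, and tests the
#' resulting fractions against the chance level 1/K with the exact two-sided
#' signed-rank test.
#'
#' @param gen Trained `cag_generator`.
#' @param clf Trained `task_classifier`.
#' @param ds [labeled_dataset] providing both source maps and the injection
#'   targets (the validation set).
#' @param n_features Number of features (default 12; fewer than 5 is refused
#'   as underpowered).
#' @param n_iter Exaggeration iterations (default 8).
#' @param seed Seed for source and target draws.
#' @return List with `results` (data.frame: feature, source_id, target,
#'   fraction), `mean`, `sd`, `chance`, and `test` (from
#'   [exact_signed_rank_test]).
#' @export
feature_battery <- function(gen, clf, ds, n_features = 12L, n_iter = 8L,
                            seed = 1L) {
  if (n_features < 5L)
    stop("n_features < 5 refused: the signed-rank test would be underpowered")
  K <- length(ds$class_names)
  set.seed(seed)
  src <- sample.int(length(ds$maps), n_features, replace = n_features > length(ds$maps))
  rows <- vector("list", n_features)
  for (i in seq_len(n_features)) {
    m <- ds$maps[[src[i]]]
    own <- if (!is.na(m$label)) m$label else clf_assign_maps(clf, list(m))
    tg <- sample(setdiff(0:(K - 1L), own), 1L)
    traj <- exaggerate(gen, m, tg, n = n_iter)
    feat <- extract_feature(traj, iter_late = n_iter,
                            iter_early = min(3L, n_iter - 1L))
    rows[[i]] <- data.frame(feature = i, source_id = m$id, target = tg,
                            fraction = inject_and_evaluate(clf, feat, ds))
  }
  res <- do.call(rbind, rows)
  chance <- 1 / K
  list(results = res, mean = mean(res$fraction), sd = stats::sd(res$fraction),
       chance = chance,
       test = exact_signed_rank_test(res$fraction, mu = chance))
}
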