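#' Counterfactual explanation of a classified activation map
#'
#' Translates the original map toward `target` with the generator and returns
#' the counterfactual together with the explanation map
#' `ce = counterfactual - original` (pixelwise, exactly; zero outside the
#' mask).  Positive CE regions are activation the classifier would have
#' needed to see to assign `target`; negative regions argue against it.
#'
#' @param gen A `cag_generator` (or toy function `(maps, targets) -> maps`).
#' @param clf The classifier being explained (stored for provenance; may be
#'   `NULL`).
#' @param map The original [activation_map].
#' @param target 0-based target class; must differ from `source_class`.
#' @param source_class 0-based source class (defaults to the map's label, or
#'   the classifier's assignment when the label is missing).
#' @return A `counterfactual_explanation` with fields `original`,
#'   `counterfactual`, `ce`, `source_class`, `target_class`.
#' @export
explain <- function(gen, clf, map, target, source_class = NULL) {
  stopifnot(inherits(map, "activation_map"))
  if (is.null(source_class)) {
    source_class <- if (!is.na(map$label)) map$label
                    else if (!is.null(clf)) predict(clf, map)$class
                    else stop("source_class required for an unlabeled map")
  }
  target <- as.integer(target)
  if (target == source_class)
    stop("target class equals source class; a counterfactual needs a different target")
  cf <- if (is.function(gen)) gen(list(map), target)[[1]]
        else generate_counterfactual(gen, map, target)
  ce <- cf$values - map$values
  ce[!map$mask] <- 0
  # floating-point subtraction is not exactly invertible; re-deriving the
  # counterfactual as original + ce (a <= 1 ulp adjustment) makes the
  # additivity identity ce + original = counterfactual hold bit-exactly
  cf <- activation_map(map$values + ce, map$mask, label = cf$label, id = cf$id)
  structure(list(original = map, counterfactual = cf, ce = ce,
                 source_class = as.integer(source_class),
                 target_class = target),
            class = "counterfactual_explanation")
}

#' @export
print.counterfactual_explanation <- function(x, ...) {
  cat(sprintf("counterfactual_explanation: '%s' class %d -> %d, |CE| max %.4f\n",
              x$original$id, x$source_class, x$target_class, max(abs(x$ce))))
  invisible(x)
}

# Percentile of a vector with linear interpolation between order statistics.
pctl <- function(v, p) stats::quantile(v, p / 100, type = 7, names = FALSE)

#' Percentile-threshold a counterfactual explanation map
#'
#' In-mask pixels whose ranking statistic falls strictly below the alpha-th
#' percentile of that statistic (computed over in-mask pixels, linear
#' interpolation) are set to zero.  `alpha = 0` leaves the CE unchanged;
#' `alpha = 100` zeroes it entirely, so adding the result back to the
#' original recovers the counterfactual and the original respectively.
#'
#' @param ce Numeric CE matrix (e.g. `explanation$ce`).
#' @param alpha Percentile threshold in \[0, 100\].
#' @param mask Logical mask; defaults to all pixels with nonzero potential
#'   (use the map's mask).
#' @param ranking `"absolute"` ranks by `|ce|` (robustness-perturbation
#'   reading); `"signed"` ranks by the signed value.
#' @return The thresholded CE matrix.
#' @export
threshold_ce <- function(ce, alpha, mask = NULL, ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  if (alpha < 0 || alpha > 100) stop("alpha must lie in [0, 100]")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ce), ncol(ce))
  out <- ce
  out[!mask] <- 0
  if (alpha == 0) return(out)
  if (alpha == 100) { out[] <- 0; return(out) }
  stat <- if (ranking == "absolute") abs(ce) else ce
  thr <- pctl(stat[mask], alpha)
  kill <- mask & (stat < thr)
  out[kill] <- 0
  out
}

#' Class-mean difference control explanation
#'
#' The univariate baseline against which CE maps are compared:
#' `mean(target-class maps) - mean(source-class maps)`, masked.
#'
#' @param ds A [labeled_dataset] containing both classes.
#' @param source_class,target_class 0-based class indices.
#' @return Numeric matrix (the delta-average map).
#' @export
control_delta_ave <- function(ds, source_class, target_class) {
  cm <- class_means(ds)
  ms <- cm[[source_class + 1L]]; mt <- cm[[target_class + 1L]]
  if (is.null(ms) || is.null(mt)) stop("empty class in delta-average control")
  d <- mt - ms
  d[!ds_mask(ds)] <- 0
  d
}

# Build explanation cases.  Each case is a list(map, target, explanation).
build_cases <- function(gen, clf, maps, targets) {
  lapply(seq_along(maps), function(i)
    explain(gen, clf, maps[[i]], targets[i]))
}

#' Perturbation-robustness sweep over percentile thresholds
#'
#' For each explanation and each `alpha`, the thresholded CE is added back to
#' the original activation, the sum is min-max normalized, classified, and
#' the number of cases assigned their target class is counted.
#'
#' @param clf The `task_classifier`.
#' @param cases List of `counterfactual_explanation` objects.
#' @param alphas Percentile thresholds (default `seq(0, 100, by = 20)`).
#' @param ranking Passed to [threshold_ce].
#' @return A `perturbation_sweep` data.frame with columns `alpha`, `count`,
#'   `percent`, plus attribute `n_cases`.
#' @export
perturbation_sweep <- function(clf, cases, alphas = seq(0, 100, by = 20),
                               ranking = "absolute") {
  if (!length(cases)) stop("empty case set")
  targets <- vapply(cases, `[[`, integer(1), "target_class")
  counts <- integer(length(alphas))
  for (ai in seq_along(alphas)) {
    perturbed <- lapply(cases, function(cs) {
      cea <- threshold_ce(cs$ce, alphas[ai], cs$original$mask, ranking)
      newv <- normalize_matrix(cs$original$values + cea, cs$original$mask)
      activation_map(newv, cs$original$mask, id = cs$original$id)
    })
    counts[ai] <- sum(clf_assign_maps(clf, perturbed) == targets)
  }
  out <- data.frame(alpha = alphas, count = counts,
                    percent = 100 * counts / length(cases))
  attr(out, "n_cases") <- length(cases)
  class(out) <- c("perturbation_sweep", class(out))
  out
}

#' Grid search for the control-mixing coefficient kappa
#'
#' For each kappa on the grid, `original + kappa * delta_ave` is normalized
#' and classified; returns the kappa maximizing the number of cases assigned
#' the target class (ties broken toward the smallest kappa).
#'
#' @param clf The `task_classifier`.
#' @param cases List of `counterfactual_explanation` objects sharing one
#'   (source, target) class pair.
#' @param delta_ave The control map from [control_delta_ave].
#' @param grid Kappa grid (default `seq(0, 5, by = 0.1)`, 51 values).
#' @return List with `kappa` (the maximizer), `count`, and `counts` (the full
#'   per-kappa count vector).
#' @export
kappa_search <- function(clf, cases, delta_ave, grid = seq(0, 5, by = 0.1)) {
  if (!length(cases)) stop("empty case set")
  targets <- vapply(cases, `[[`, integer(1), "target_class")
  counts <- integer(length(grid))
  for (gi in seq_along(grid)) {
    mixed <- lapply(cases, function(cs)
      activation_map(normalize_matrix(cs$original$values + grid[gi] * delta_ave,
                                      cs$original$mask),
                     cs$original$mask, id = cs$original$id))
    counts[gi] <- sum(clf_assign_maps(clf, mixed) == targets)
  }
  best <- which.max(counts)
  list(kappa = grid[best], count = counts[best], counts = counts)
}

#' Counterfactual evaluation protocol for correctly classified maps
#'
#' Selects the held-out maps the classifier assigns to their true class,
#' draws one random incorrect target class per case (seeded), builds the
#' explanations, and runs the perturbation sweep; optionally runs the
#' delta-average control per (source, target) pair.
#'
#' @param gen Trained `cag_generator`.
#' @param clf Trained `task_classifier`.
#' @param ds Held-out [labeled_dataset].
#' @param alphas Sweep thresholds.
#' @param ranking Passed to [threshold_ce].
#' @param control Run the kappa control analysis (uses `control_ds` for class
#'   means, default `ds`).
#' @param control_ds Dataset from which class-mean maps are computed.
#' @param seed Seed for the random target draw.
#' @return List with `cases`, `sweep`, and (optionally) `control` (one row
#'   per class pair: source, target, kappa, count, n).
#' @export
explain_correct <- function(gen, clf, ds, alphas = seq(0, 100, by = 20),
                            ranking = "absolute", control = FALSE,
                            control_ds = ds, seed = 1L) {
  labs <- ds_labels(ds)
  pred <- clf_assign_maps(clf, ds$maps)
  sel <- which(pred == labs)
  if (!length(sel)) stop("no correctly classified maps in the dataset")
  K <- length(ds$class_names)
  set.seed(seed)
  targets <- vapply(labs[sel], function(y)
    sample(setdiff(0:(K - 1L), y), 1L), integer(1))
  cases <- build_cases(gen, clf, ds$maps[sel], targets)
  out <- list(cases = cases,
              sweep = perturbation_sweep(clf, cases, alphas, ranking))
  if (control) out$control <- run_kappa_control(clf, cases, control_ds)
  out
}

#' Counterfactual explanation of misclassified maps
#'
#' Selects maps the classifier assigns to a class other than their true
#' label, targets the translation at the true class, and runs the same CE,
#' sweep, and (optionally) control machinery.
#'
#' @inheritParams explain_correct
#' @return As [explain_correct].
#' @export
explain_misclassification <- function(gen, clf, ds,
                                      alphas = seq(0, 100, by = 20),
                                      ranking = "absolute", control = FALSE,
                                      control_ds = ds) {
  labs <- ds_labels(ds)
  pred <- clf_assign_maps(clf, ds$maps)
  sel <- which(pred != labs)
  if (!length(sel)) stop("no misclassified maps in the dataset")
  cases <- lapply(sel, function(i)
    explain(gen, clf, ds$maps[[i]], target = labs[i], source_class = pred[i]))
  out <- list(cases = cases,
              sweep = perturbation_sweep(clf, cases, alphas, ranking))
  if (control) out$control <- run_kappa_control(clf, cases, control_ds)
  out
}

# Group cases by (source, target) pair and run kappa_search per pair.
run_kappa_control <- function(clf, cases, control_ds) {
  key <- vapply(cases, function(cs)
    paste(cs$source_class, cs$target_class), character(1))
  rows <- lapply(unique(key), function(k) {
    grp <- cases[key == k]
    sc <- grp[[1]]$source_class; tc <- grp[[1]]$target_class
    dav <- control_delta_ave(control_ds, sc, tc)
    ks <- kappa_search(clf, grp, dav)
    data.frame(source = sc, target = tc, kappa = ks$kappa,
               count = ks$count, n = length(grp))
  })
  do.call(rbind, rows)
}

#' Write a perturbation sweep as CSV
#' @param sweep A `perturbation_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
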