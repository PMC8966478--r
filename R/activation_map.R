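#' Masked 2D activation maps and labeled datasets
#'
#' An `activation_map` is one masked grayscale activation image: a numeric
#' H x W matrix of values in \[0, 1\], a logical H x W brain mask, an optional
#' 0-based class label, and an id.  Pixels outside the mask are exactly zero.
#' A `labeled_dataset` is an ordered collection of maps sharing one mask and
#' one class-name vector; it is the container every downstream stage (the
#' task classifier, the counterfactual generator, the evaluation protocols)
#' consumes.
#'
#' @param values Numeric H x W matrix.
#' @param mask Logical H x W matrix, `TRUE` inside the brain.
#' @param label Optional integer class index in `0..K-1` (`NA` for unlabeled).
#' @param id Character identifier.
#' @return An object of class `activation_map`.
#' @examples
#' m <- activation_map(matrix(runif(12), 3, 4), matrix(TRUE, 3, 4))
#' dim(m$values)
#' @export
activation_map <- function(values, mask, label = NA_integer_, id = "map") {
  values <- as.matrix(values)
  mask <- if (is.null(dim(mask)))
    matrix(as.logical(mask), nrow(values), ncol(values))
  else matrix(as.logical(mask), nrow(mask), ncol(mask))
  stopifnot(identical(dim(values), dim(mask)), all(is.finite(values)))
  values[!mask] <- 0
  structure(list(values = values, mask = mask,
                 label = as.integer(label), id = as.character(id)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation_map '%s': %d x %d, %d in-mask px, label %s\n",
              x$id, nrow(x$values), ncol(x$values), sum(x$mask),
              ifelse(is.na(x$label), "none", x$label)))
  invisible(x)
}

#' Construct a labeled dataset of activation maps
#'
#' @param maps List of [activation_map] objects sharing shape and mask.
#' @param class_names Character vector of K class names; labels index into it
#'   0-based.
#' @param config Optional generation config stored for provenance.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(maps, class_names, config = NULL) {
  K <- length(class_names)
  if (length(maps)) {
    m0 <- maps[[1]]
    for (m in maps) {
      stopifnot(inherits(m, "activation_map"),
                identical(dim(m$values), dim(m0$values)),
                identical(m$mask, m0$mask))
      if (!is.na(m$label)) stopifnot(m$label >= 0L, m$label < K)
    }
  }
  structure(list(maps = maps, class_names = class_names, config = config),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d maps, %d classes (%s)\n",
              length(x$maps), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$maps)

ds_labels <- function(ds) vapply(ds$maps, function(m) m$label, integer(1))

ds_mask <- function(ds) if (length(ds$maps)) ds$maps[[1]]$mask else NULL

# Stack a list of maps into a flat (1, H, W, B) array for the networks.
maps_to_array <- function(maps) {
  stopifnot(length(maps) > 0)
  d <- dim(maps[[1]]$values)
  arr <- vapply(maps, function(m) m$values, maps[[1]]$values)
  array(aperm(arr, c(1, 2, 3)), c(1L, d[1], d[2], length(maps)))
}

array_to_maps <- function(arr, mask, ids = NULL, labels = NULL) {
  d <- dim(arr)
  B <- d[4]
  lapply(seq_len(B), function(b) {
    activation_map(matrix(arr[1, , , b], d[2], d[3]), mask,
                   label = if (is.null(labels)) NA_integer_ else labels[b],
                   id = if (is.null(ids)) sprintf("map%03d", b) else ids[b])
  })
}

#' Default two-sheet brain mask
#'
#' Union of two ellipses side by side, emulating the two flattened cortical
#' sheets (left/right hemisphere) of a flat-map montage.
#'
#' @param H,W Mask dimensions in pixels.
#' @return Logical H x W matrix.
#' @export
sheet_mask <- function(H, W) {
  r <- (seq_len(H) - (H + 1) / 2) / (0.48 * H)
  cl <- (seq_len(W) - (W + 1) * 0.27) / (0.23 * W)
  cr <- (seq_len(W) - (W + 1) * 0.73) / (0.23 * W)
  m <- outer(r^2, cl^2, "+") <= 1 | outer(r^2, cr^2, "+") <= 1
  m
}

#' Configuration for the synthetic activation-map generator
#'
#' The generator emulates the structure of multi-task cortical flat-map
#' z-maps: all classes share a smooth background pattern, each class adds its
#' own localized activation blobs at class-specific locations, each subject
#' adds i.i.d. Gaussian noise, and everything lives on a fixed brain mask.
#'
#' @param H,W Map size in pixels (default 32 x 64).
#' @param K Number of classes (default 7, mirroring the seven-task setting).
#' @param n_per_class Maps per class (default 40).
#' @param background_amplitude Amplitude of the shared smooth background.
#' @param class_amplitude Peak amplitude of the class-specific blobs.
#' @param noise_sd Standard deviation of per-subject additive Gaussian noise.
#' @param blob_width Gaussian blob width (sd, in pixels).
#' @param n_blobs Blobs per class (at least 2 distinct centers).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(H = 32L, W = 64L, K = 7L, n_per_class = 40L,
                         background_amplitude = 0.25, class_amplitude = 0.5,
                         noise_sd = 0.05, blob_width = 3, n_blobs = 2L,
                         seed = 1L) {
  stopifnot(H >= 1, W >= 1, K >= 1, n_per_class >= 0,
            background_amplitude >= 0, class_amplitude >= 0, noise_sd >= 0,
            blob_width > 0, n_blobs >= 2)
  structure(list(H = as.integer(H), W = as.integer(W), K = as.integer(K),
                 n_per_class = as.integer(n_per_class),
                 background_amplitude = background_amplitude,
                 class_amplitude = class_amplitude,
                 noise_sd = noise_sd, blob_width = blob_width,
                 n_blobs = as.integer(n_blobs), seed = as.integer(seed)),
            class = "synth_config")
}

gaussian_blob <- function(H, W, ch, cw, width) {
  outer(exp(-(seq_len(H) - ch)^2 / (2 * width^2)),
        exp(-(seq_len(W) - cw)^2 / (2 * width^2)))
}

# Class blob centers: drawn inside the mask with a minimum pairwise distance
# so centers are disjoint across (and within) classes.  Greedy pass over a
# shuffled pixel list; the spacing relaxes (halves) if the mask is too small
# to hold n centers at the requested distance.
draw_centers <- function(mask, n, min_dist) {
  idx <- which(mask, arr.ind = TRUE)
  ord <- idx[sample.int(nrow(idx)), , drop = FALSE]
  d <- min_dist
  repeat {
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(ord))) {
      cand <- ord[i, ]
      if (!nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= d)
        centers <- rbind(centers, cand)
      if (nrow(centers) == n) return(centers)
    }
    d <- d / 2
    if (d < 1) stop("could not place disjoint blob centers; mask too small")
  }
}

#' Generate a synthetic multi-class activation-map dataset
#'
#' Each class mean is a shared smooth background plus `n_blobs` localized
#' positive Gaussian blobs at class-specific, pairwise disjoint centers.
#' Individual maps add zero-mean Gaussian noise (`noise_sd`), are clipped to
#' \[0, 1\], min-max normalized within the mask so every stored map spans
#' exactly \[0, 1\], and zeroed outside the mask.
#'
#' @param cfg A [synth_config].
#' @param mask Optional logical mask (default [sheet_mask]); must contain at
#'   least one `TRUE` pixel.
#' @param class_names Optional class names (default "class0".."class{K-1}"
#'   or, for K = 7, the seven canonical task names).
#' @return A [labeled_dataset] with `K * n_per_class` maps.
#' @examples
#' ds <- generate_synthetic_dataset(synth_config(H = 16, W = 32, n_per_class = 2))
#' length(ds)
#' @export
generate_synthetic_dataset <- function(cfg = synth_config(), mask = NULL,
                                       class_names = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(mask)) mask <- sheet_mask(cfg$H, cfg$W)
  mask <- matrix(as.logical(mask), cfg$H, cfg$W)
  if (!any(mask)) stop("degenerate mask: no in-mask pixels")
  if (is.null(class_names)) {
    class_names <- if (cfg$K == 7L)
      c("EMOTION", "GAMBLING", "LANGUAGE", "MOTOR", "RELATIONAL", "SOCIAL", "WM")
    else paste0("class", seq_len(cfg$K) - 1L)
  }
  stopifnot(length(class_names) == cfg$K)
  set.seed(cfg$seed)
  # shared smooth background: a few broad bumps, identical for all classes
  bg <- matrix(0, cfg$H, cfg$W)
  for (i in 1:4) {
    ch <- runif(1, 1, cfg$H); cw <- runif(1, 1, cfg$W)
    bg <- bg + gaussian_blob(cfg$H, cfg$W, ch, cw, 0.25 * min(cfg$H, cfg$W))
  }
  bg <- cfg$background_amplitude * bg / max(bg)
  min_dist <- max(3 * cfg$blob_width, 4)
  centers <- draw_centers(mask, cfg$K * cfg$n_blobs, min_dist)
  class_mean <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    pat <- matrix(0, cfg$H, cfg$W)
    rows <- (k - 1L) * cfg$n_blobs + seq_len(cfg$n_blobs)
    for (r in rows)
      pat <- pat + gaussian_blob(cfg$H, cfg$W, centers[r, 1], centers[r, 2],
                                 cfg$blob_width)
    class_mean[[k]] <- 0.15 + bg + cfg$class_amplitude * pat
  }
  maps <- vector("list", cfg$K * cfg$n_per_class)
  i <- 0L
  for (k in seq_len(cfg$K)) {
    for (j in seq_len(cfg$n_per_class)) {
      v <- class_mean[[k]]
      if (cfg$noise_sd > 0)
        v <- v + matrix(rnorm(cfg$H * cfg$W, sd = cfg$noise_sd), cfg$H, cfg$W)
      v <- pmin(pmax(v, 0), 1)
      v[!mask] <- 0
      rng <- range(v[mask])
      if (rng[2] > rng[1]) v[mask] <- (v[mask] - rng[1]) / (rng[2] - rng[1])
      i <- i + 1L
      maps[[i]] <- activation_map(v, mask, label = k - 1L,
                                  id = sprintf("%s_%03d", class_names[k], j))
    }
  }
  labeled_dataset(maps, class_names, config = cfg)
}

#' Class-mean maps of a labeled dataset
#' @param ds A [labeled_dataset].
#' @return List of K matrices (classes with no maps give `NULL`).
#' @export
class_means <- function(ds) {
  K <- length(ds$class_names)
  labs <- ds_labels(ds)
  lapply(seq_len(K) - 1L, function(k) {
    sel <- which(labs == k)
    if (!length(sel)) return(NULL)
    Reduce(`+`, lapply(ds$maps[sel], function(m) m$values)) / length(sel)
  })
}

# 1D area-overlap weight matrix mapping `n` source cells onto `t` target
# cells; rows sum to 1, so constants are preserved exactly.
area_weights <- function(n, t) {
  w <- matrix(0, t, n)
  sz <- n / t
  for (i in seq_len(t)) {
    lo <- (i - 1) * sz; hi <- i * sz
    j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov / sz
    }
  }
  w
}

#' Downsample an activation map by area-weighted averaging
#'
#' Values are averaged with exact cell-overlap areas (so the global mean of an
#' unmasked image is preserved); the mask is downsampled by majority vote
#' (in-mask area fraction >= 0.5) and re-applied.
#'
#' @param map An [activation_map].
#' @param target_h,target_w Target dimensions, `1 <= target <= source`.
#' @return A downsampled [activation_map].
#' @examples
#' m <- activation_map(matrix(c(0, 1, 1, 0), 2, 2), matrix(TRUE, 2, 2))
#' downsample(m, 1, 1)$values
#' @export
downsample <- function(map, target_h, target_w) {
  stopifnot(inherits(map, "activation_map"))
  H <- nrow(map$values); W <- ncol(map$values)
  if (target_h < 1 || target_w < 1) stop("target dimensions must be positive")
  if (target_h > H || target_w > W) stop("target dimensions exceed source")
  Lh <- area_weights(H, as.integer(target_h))
  Lw <- area_weights(W, as.integer(target_w))
  vals <- Lh %*% map$values %*% t(Lw)
  mfrac <- Lh %*% (map$mask + 0) %*% t(Lw)
  mk <- mfrac >= 0.5
  vals[!mk] <- 0
  activation_map(vals, mk, label = map$label, id = map$id)
}

#' Min-max normalize an activation map within its mask
#'
#' Affine rescale over in-mask pixels so the in-mask minimum maps to 0 and the
#' maximum to 1; out-of-mask pixels stay 0.  A constant in-mask image is a
#' degenerate input and raises an error.
#'
#' @param map An [activation_map].
#' @return The normalized [activation_map].
#' @export
minmax_normalize <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  v <- map$values[map$mask]
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate normalization: map is constant within the mask")
  out <- map$values
  out[map$mask] <- (v - rng[1]) / (rng[2] - rng[1])
  out[!map$mask] <- 0
  activation_map(out, map$mask, label = map$label, id = map$id)
}

# normalize if non-degenerate; raw numeric-matrix variant used by the
# evaluation protocols (values may leave [0,1] after additions).
normalize_matrix <- function(values, mask) {
  v <- values[mask]
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate normalization: constant within the mask")
  out <- values
  out[mask] <- (v - rng[1]) / (rng[2] - rng[1])
  out[!mask] <- 0
  out
}

#' Split a labeled dataset into train and held-out parts, stratified by class
#'
#' @param ds A [labeled_dataset].
#' @param n_holdout_per_class Held-out maps per class.
#' @param seed Seed for the stratified draw.
#' @return List with elements `train` and `holdout`.
#' @export
split_dataset <- function(ds, n_holdout_per_class, seed = 1L) {
  labs <- ds_labels(ds)
  set.seed(seed)
  hold <- unlist(lapply(unique(labs), function(k) {
    sel <- which(labs == k)
    sample(sel, min(n_holdout_per_class, length(sel)))
  }))
  list(train = labeled_dataset(ds$maps[-hold], ds$class_names, ds$config),
       holdout = labeled_dataset(ds$maps[hold], ds$class_names, ds$config))
}
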