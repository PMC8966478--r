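# Toy generators, classifiers and small fixtures shared across tests.
# All fixtures are built in code; nothing is read from disk.

# Translation stubs with the generator calling convention (maps, targets).
identity_gen <- function(maps, targets) maps

make_delta_gen <- function(delta) {
  function(maps, targets) lapply(maps, function(m)
    activation_map(m$values + delta * m$mask, m$mask, label = m$label, id = m$id))
}

# Deterministic pseudo-random toy generator: a reproducible, target-dependent
# smooth perturbation (independent of the network code paths).
make_wiggle_gen <- function(scale = 0.1) {
  function(maps, targets) {
    targets <- rep_len(targets, length(maps))
    lapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      d <- dim(m$values)
      ph <- outer(seq_len(d[1]), seq_len(d[2]), function(r, c)
        sin(r / 2 + targets[i]) * cos(c / 3 + targets[i]))
      activation_map(pmin(pmax(m$values + scale * ph * m$mask, 0), 1),
                     m$mask, label = m$label, id = m$id)
    })
  }
}

# Probability-matrix stubs with the (maps) -> K x B calling convention.
make_const_prob_clf <- function(p) function(maps) {
  matrix(rep(p, length(maps)), length(p), length(maps))
}

# Small labeled dataset on a full mask, two blobby classes.
tiny_dataset <- function(H = 8L, W = 16L, K = 2L, n_per_class = 4L,
                         seed = 7L, noise_sd = 0.04) {
  generate_synthetic_dataset(
    synth_config(H = H, W = W, K = K, n_per_class = n_per_class,
                 noise_sd = noise_sd, blob_width = 1.5, seed = seed))
}

# Nearest-class-mean classifier as a plain assignment function (maps -> class).
nearest_mean_clf <- function(ds) {
  cm <- class_means(ds)
  function(maps) {
    vapply(maps, function(m)
      which.min(vapply(cm, function(x) sum((m$values - x)^2), numeric(1))) - 1L,
      integer(1))
  }
}

expect_same_values <- function(a, b) expect_identical(unname(a), unname(b))
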