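# Run configuration and pipeline commands tying the stages into reproducible
# experiments: synth -> train_classifier -> train_cag -> explain / sweep /
# exaggerate.  One YAML file holds every hyperparameter; one global seed
# drives all stages; every command writes a manifest (config snapshot, seed,
# package version, artifact hashes) sufficient to reproduce its artifacts.

#' Default run configuration
#'
#' @param dir Directory for all artifacts.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param synth,classifier,cag_train,weights Optional sub-config overrides
#'   ([synth_config], [classifier_config], [cag_train_config],
#'   [loss_weights]).
#' @param n_holdout_per_class Held-out maps per class carved from the
#'   synthetic dataset.
#' @param alphas Sweep thresholds.
#' @param ranking CE percentile ranking statistic.
#' @param n_features Feature-battery size.
#' @return A `run_config` list.
#' @export
run_config <- function(dir = "cagen_run", seed = 1L,
                       synth = synth_config(seed = seed),
                       classifier = classifier_config(seed = seed + 1L),
                       cag_train = cag_train_config(seed = seed + 2L),
                       weights = loss_weights(),
                       n_holdout_per_class = 10L,
                       alphas = seq(0, 100, by = 20),
                       ranking = "absolute", n_features = 12L) {
  structure(list(dir = dir, seed = as.integer(seed), synth = synth,
                 classifier = classifier, cag_train = cag_train,
                 weights = weights,
                 n_holdout_per_class = as.integer(n_holdout_per_class),
                 alphas = alphas, ranking = ranking,
                 n_features = as.integer(n_features)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param cfg A [run_config].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the [run_config].
#' @export
write_run_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), function(x) x, how = "replace")
  plain$synth <- unclass(cfg$synth)
  plain$classifier <- unclass(cfg$classifier)
  plain$cag_train <- unclass(cfg$cag_train)
  plain$weights <- unclass(cfg$weights)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  y <- yaml::read_yaml(path)
  cc <- y$classifier
  cc$conv_blocks <- lapply(cc$conv_blocks, as.integer)
  run_config(dir = y$dir, seed = y$seed,
             synth = do.call(synth_config, y$synth),
             classifier = do.call(classifier_config, cc),
             cag_train = do.call(cag_train_config,
                                 y$cag_train[!vapply(y$cag_train, is.null, TRUE)]),
             weights = do.call(loss_weights, y$weights),
             n_holdout_per_class = y$n_holdout_per_class,
             alphas = y$alphas, ranking = y$ranking,
             n_features = y$n_features)
}

run_paths <- function(cfg) {
  d <- cfg$dir
  list(train = file.path(d, "dataset_train.cagd"),
       holdout = file.path(d, "dataset_holdout.cagd"),
       classifier = file.path(d, "classifier.ckpt"),
       clf_history = file.path(d, "classifier_history.csv"),
       generator = file.path(d, "generator.ckpt"),
       discriminator = file.path(d, "discriminator.ckpt"),
       cag_history = file.path(d, "cag_history.csv"),
       sweep_correct = file.path(d, "sweep_correct.csv"),
       sweep_incorrect = file.path(d, "sweep_incorrect.csv"),
       battery = file.path(d, "feature_battery.csv"),
       battery_json = file.path(d, "feature_battery.json"))
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

write_manifest <- function(cfg, cmd, artifacts) {
  p <- file.path(cfg$dir, paste0("manifest_", cmd, ".json"))
  existing <- artifacts[file.exists(artifacts)]
  m <- list(command = cmd, seed = cfg$seed,
            package_version = as.character(utils::packageVersion("cagen")),
            timestamp = format(Sys.time(), tz = "UTC"),
            config = strip_classes(cfg),
            artifacts = as.list(unname(tools::md5sum(existing))))
  names(m$artifacts) <- basename(existing)
  jsonlite::write_json(m, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(p)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run ", producer, " first")
  path
}

#' Pipeline commands
#'
#' Each command reads its inputs from `cfg$dir`, writes its artifacts there,
#' and records a manifest.  Commands are deterministic given an identical
#' config and seed (existing artifacts are overwritten).
#'
#' `cmd_synth` generates the synthetic dataset and carves off the stratified
#' holdout; `cmd_train_classifier` trains the task classifier;
#' `cmd_train_cag` trains the generator against the frozen classifier;
#' `cmd_explain` writes per-case counterfactual summaries for correct and
#' incorrect classifications; `cmd_sweep` writes the perturbation-sweep
#' tables; `cmd_exaggerate` runs the feature battery.
#'
#' @param cfg A [run_config] (or path to its YAML file).
#' @return Invisibly, a list of the artifact paths written.
#' @export
cmd_synth <- function(cfg) {
  cfg <- as_run_config(cfg)
  dir.create(cfg$dir, showWarnings = FALSE, recursive = TRUE)
  pt <- run_paths(cfg)
  full <- generate_synthetic_dataset(cfg$synth)
  sp <- split_dataset(full, cfg$n_holdout_per_class, seed = cfg$seed)
  save_dataset(sp$train, pt$train)
  save_dataset(sp$holdout, pt$holdout)
  write_manifest(cfg, "synth", c(pt$train, pt$holdout))
  invisible(list(train = pt$train, holdout = pt$holdout))
}

#' @rdname cmd_synth
#' @export
cmd_train_classifier <- function(cfg) {
  cfg <- as_run_config(cfg)
  pt <- run_paths(cfg)
  ds <- load_dataset(require_artifact(pt$train, "cmd_synth"))
  d <- dim(ds$maps[[1]]$values)
  clf <- build_classifier(cfg$classifier, d)
  fit <- train_classifier(clf, ds, cfg$classifier)
  save_classifier(fit$classifier, pt$classifier)
  utils::write.csv(fit$history, pt$clf_history, row.names = FALSE)
  write_manifest(cfg, "train_classifier", c(pt$classifier, pt$clf_history))
  invisible(list(classifier = pt$classifier, history = pt$clf_history))
}

#' @rdname cmd_synth
#' @export
cmd_train_cag <- function(cfg) {
  cfg <- as_run_config(cfg)
  pt <- run_paths(cfg)
  ds <- load_dataset(require_artifact(pt$train, "cmd_synth"))
  clf <- load_classifier(require_artifact(pt$classifier, "cmd_train_classifier"))
  res <- train_cag(clf, ds, cfg$weights, cfg$cag_train)
  save_cag_net(res$gen, pt$generator)
  save_cag_net(res$disc, pt$discriminator)
  utils::write.csv(res$history, pt$cag_history, row.names = FALSE)
  write_manifest(cfg, "train_cag",
                 c(pt$generator, pt$discriminator, pt$cag_history))
  invisible(list(generator = pt$generator, discriminator = pt$discriminator,
                 history = pt$cag_history))
}

load_stage3 <- function(cfg) {
  pt <- run_paths(cfg)
  list(pt = pt,
       holdout = load_dataset(require_artifact(pt$holdout, "cmd_synth")),
       train = load_dataset(require_artifact(pt$train, "cmd_synth")),
       clf = load_classifier(require_artifact(pt$classifier, "cmd_train_classifier")),
       gen = load_cag_net(require_artifact(pt$generator, "cmd_train_cag")))
}

#' @rdname cmd_synth
#' @export
cmd_explain <- function(cfg) {
  cfg <- as_run_config(cfg)
  s <- load_stage3(cfg)
  labs <- ds_labels(s$holdout)
  pred <- predict(s$clf, s$holdout)$class
  K <- length(s$holdout$class_names)
  set.seed(cfg$seed)
  rows <- lapply(seq_along(s$holdout$maps), function(i) {
    correct <- pred[i] == labs[i]
    tg <- if (correct) sample(setdiff(0:(K - 1L), labs[i]), 1L) else labs[i]
    ex <- explain(s$gen, s$clf, s$holdout$maps[[i]], tg,
                  source_class = pred[i])
    cfc <- predict(s$clf, minmax_normalize(ex$counterfactual))$class
    data.frame(id = s$holdout$maps[[i]]$id, true = labs[i], assigned = pred[i],
               correct = correct, target = tg, cf_assigned = cfc)
  })
  out <- do.call(rbind, rows)
  p <- file.path(cfg$dir, "explanations.csv")
  utils::write.csv(out, p, row.names = FALSE)
  write_manifest(cfg, "explain", p)
  invisible(list(explanations = p))
}

#' @rdname cmd_synth
#' @export
cmd_sweep <- function(cfg) {
  cfg <- as_run_config(cfg)
  s <- load_stage3(cfg)
  res_c <- explain_correct(s$gen, s$clf, s$holdout, alphas = cfg$alphas,
                           ranking = cfg$ranking, seed = cfg$seed)
  write_sweep_csv(res_c$sweep, s$pt$sweep_correct)
  arts <- s$pt$sweep_correct
  mis <- tryCatch(
    explain_misclassification(s$gen, s$clf, s$holdout, alphas = cfg$alphas,
                              ranking = cfg$ranking),
    error = function(e) NULL)
  if (!is.null(mis)) {
    write_sweep_csv(mis$sweep, s$pt$sweep_incorrect)
    arts <- c(arts, s$pt$sweep_incorrect)
  }
  write_manifest(cfg, "sweep", arts)
  invisible(list(correct = s$pt$sweep_correct,
                 incorrect = if (!is.null(mis)) s$pt$sweep_incorrect))
}

#' @rdname cmd_synth
#' @export
cmd_exaggerate <- function(cfg) {
  cfg <- as_run_config(cfg)
  s <- load_stage3(cfg)
  bat <- feature_battery(s$gen, s$clf, s$holdout,
                         n_features = cfg$n_features, seed = cfg$seed)
  utils::write.csv(bat$results, s$pt$battery, row.names = FALSE)
  jsonlite::write_json(list(mean = bat$mean, sd = bat$sd, chance = bat$chance,
                            statistic = bat$test$statistic,
                            p_value = bat$test$p_value,
                            n = nrow(bat$results)),
                       s$pt$battery_json, auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "exaggerate", c(s$pt$battery, s$pt$battery_json))
  invisible(list(battery = s$pt$battery, summary = s$pt$battery_json))
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) cfg
  else if (is.character(cfg)) read_run_config(cfg)
  else stop("cfg must be a run_config or a path to a YAML run config")
}
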