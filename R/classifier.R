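#' Configuration for the task classifier CNN
#'
#' A small VGG-style stack: five convolution blocks for feature extraction
#' followed by two fully connected layers for classification, trained from
#' scratch with SGD on categorical crossentropy.  Defaults mirror the decoding
#' setup (batch size 10, 50 epochs, learning rate 1e-4, SGD, ten folds);
#' desk-scale runs typically override `lr`/`epochs`.
#'
#' @param conv_blocks List of `c(channels, kernel, stride)` triplets.
#' @param fc_widths Integer vector of hidden fully-connected widths.
#' @param K Number of classes (>= 2).
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param optimizer `"sgd"` (momentum-free) or `"adam"`.
#' @param folds Crossvalidation folds for reporting (`< 2` skips CV).
#' @param seed Integer seed controlling initialization and batch order.
#' @param replicate_seeds Optional integer vector of seeds for replicate runs.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(conv_blocks = list(c(8L, 3L, 2L), c(16L, 3L, 2L),
                                                c(32L, 3L, 2L), c(32L, 3L, 2L),
                                                c(64L, 3L, 2L)),
                              fc_widths = c(64L), K = 7L, lr = 1e-4,
                              batch_size = 10L, epochs = 50L,
                              optimizer = "sgd", folds = 10L, seed = 1L,
                              replicate_seeds = NULL) {
  stopifnot(K >= 2, lr > 0, batch_size >= 1, epochs >= 1,
            optimizer %in% c("sgd", "adam"))
  structure(list(conv_blocks = conv_blocks, fc_widths = as.integer(fc_widths),
                 K = as.integer(K), lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 folds = as.integer(folds), seed = as.integer(seed),
                 replicate_seeds = replicate_seeds),
            class = "classifier_config")
}

clf_shape_trace <- function(cfg, H, W) {
  Cin <- 1L; shapes <- list()
  for (i in seq_along(cfg$conv_blocks)) {
    bl <- cfg$conv_blocks[[i]]
    k <- bl[2]; s <- bl[3]; p <- k %/% 2L
    Ho <- (H + 2L * p - k) %/% s + 1L
    Wo <- (W + 2L * p - k) %/% s + 1L
    if (Ho < 1L || Wo < 1L)
      stop("conv stack incompatible with input shape ", H, "x", W)
    shapes[[i]] <- list(Cin = Cin, H = H, W = W, Cout = bl[1], k = k, s = s,
                        p = p, Ho = Ho, Wo = Wo)
    Cin <- bl[1]; H <- Ho; W <- Wo
  }
  list(blocks = shapes, flat = Cin * H * W)
}

#' Build an (untrained) task classifier
#'
#' Parameter initialization is deterministic given `cfg$seed`; the forward
#' pass emits a length-K probability vector (entries >= 0, summing to 1).
#'
#' @param cfg A [classifier_config].
#' @param input_shape `c(H, W)` of the activation maps.
#' @return A `task_classifier`.
#' @export
build_classifier <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "classifier_config"), length(input_shape) == 2)
  tr <- clf_shape_trace(cfg, as.integer(input_shape[1]), as.integer(input_shape[2]))
  set.seed(cfg$seed)
  par <- list()
  for (i in seq_along(tr$blocks)) {
    b <- tr$blocks[[i]]
    par[[paste0("cW", i)]] <- he_conv(b$Cout, b$Cin, b$k)
    par[[paste0("cb", i)]] <- numeric(b$Cout)
  }
  widths <- c(tr$flat, cfg$fc_widths, cfg$K)
  for (i in seq_len(length(widths) - 1L)) {
    par[[paste0("fW", i)]] <- he_dense(widths[i + 1L], widths[i])
    par[[paste0("fb", i)]] <- numeric(widths[i + 1L])
  }
  structure(list(cfg = cfg, input_shape = as.integer(input_shape),
                 K = cfg$K, trace = tr, par = par, trained = FALSE),
            class = "task_classifier")
}

# Forward pass on an adnode batch (1, H, W, B); returns (K, B) probabilities.
clf_forward <- function(clf, pn, x, B) {
  h <- x
  for (i in seq_along(clf$trace$blocks)) {
    b <- clf$trace$blocks[[i]]
    h <- ad_relu(conv2d(h, pn[[paste0("cW", i)]], pn[[paste0("cb", i)]],
                        b$Cin, b$H, b$W, B, b$k, b$s, b$p))
  }
  h <- ad_reshape(h, c(clf$trace$flat, B))
  nfc <- length(clf$cfg$fc_widths) + 1L
  for (i in seq_len(nfc)) {
    h <- dense(h, pn[[paste0("fW", i)]], pn[[paste0("fb", i)]], B)
    if (i < nfc) h <- ad_relu(h)
  }
  softmax_cols(h, clf$K, B)
}

# Numeric probabilities for a (1, H, W, B) array.
clf_probs_array <- function(clf, arr) {
  B <- dim(arr)[4]
  pn <- params_as_consts(clf$par)
  matrix(ad_value(clf_forward(clf, pn, ad_const(arr), B)), clf$K, B)
}

#' Deterministic argmax class assignment
#'
#' Ties are broken toward the lowest class index.
#'
#' @param probs K x n matrix (columns are probability vectors) or a single
#'   length-K vector.
#' @return Integer vector of 0-based class indices.
#' @export
assign_class <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
  as.integer(apply(probs, 2L, which.max) - 1L)
}

#' Predict classes and probabilities for activation maps
#'
#' @param object A trained (or untrained) `task_classifier`.
#' @param newdata A [labeled_dataset], list of [activation_map]s, or a single
#'   map.
#' @param ... Unused.
#' @return List with `class` (0-based integer vector) and `probs` (K x n
#'   matrix).
#' @export
predict.task_classifier <- function(object, newdata, ...) {
  maps <- if (inherits(newdata, "labeled_dataset")) newdata$maps
          else if (inherits(newdata, "activation_map")) list(newdata)
          else newdata
  stopifnot(length(maps) > 0)
  d <- dim(maps[[1]]$values)
  if (!identical(d, object$input_shape))
    stop("map shape ", d[1], "x", d[2], " does not match classifier input ",
         object$input_shape[1], "x", object$input_shape[2])
  probs <- matrix(0, object$K, length(maps))
  chunk <- 64L
  for (s in seq(1L, length(maps), by = chunk)) {
    e <- min(s + chunk - 1L, length(maps))
    probs[, s:e] <- clf_probs_array(object, maps_to_array(maps[s:e]))
  }
  list(class = assign_class(probs), probs = probs)
}

# Uniform access: a classifier is either a task_classifier or a plain
# function mapping a list of maps to 0-based class assignments.
clf_assign_maps <- function(clf, maps) {
  if (is.function(clf)) as.integer(clf(maps)) else predict(clf, maps)$class
}

clf_ce_and_acc <- function(clf, maps, labels) {
  p <- predict(clf, maps)
  pt <- pmax(p$probs[cbind(labels + 1L, seq_along(labels))], 1e-12)
  list(loss = -mean(log(pt)), acc = mean(p$class == labels))
}

#' Stratified fold assignment
#' @param labels Integer 0-based labels.
#' @param folds Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(labels, folds, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (k in unique(labels)) {
    sel <- sample(which(labels == k))
    fold[sel] <- rep_len(seq_len(folds), length(sel))
  }
  fold
}

clf_fit_epochs <- function(clf, maps, labels, cfg, epochs, opt_state = NULL,
                           eval_fun = NULL) {
  n <- length(maps)
  par <- clf$par
  st <- if (identical(cfg$optimizer, "adam")) adam_init(par) else NULL
  history <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[s:min(s + cfg$batch_size - 1L, n)]
      B <- length(sel)
      pn <- params_as_leaves(par)
      p <- clf_forward(clf, pn, ad_const(maps_to_array(maps[sel])), B)
      loss <- nll_cols(p, labels[sel], clf$K, B)
      gr <- ad_grad(loss, pn)
      gv <- lapply(gr, ad_value)
      names(gv) <- names(par)
      if (is.null(st)) {
        par <- sgd_step_params(par, gv, cfg$lr)
      } else {
        upd <- adam_step(par, gv, st, cfg$lr, 0.9, 0.999)
        par <- upd$par; st <- upd$st
      }
    }
    clf$par <- par
    if (!is.null(eval_fun)) history[[ep]] <- eval_fun(clf, ep)
  }
  list(clf = clf, history = history)
}

#' Train the task classifier
#'
#' Runs label-stratified k-fold crossvalidation for reporting (per-epoch
#' train/validation accuracy and loss per fold), then retrains on the full
#' dataset; the returned classifier is the full-data model.
#'
#' @param clf A `task_classifier` from [build_classifier].
#' @param ds A [labeled_dataset] with at least two classes present.
#' @param cfg Optional [classifier_config] override (default `clf$cfg`).
#' @return List with `classifier` (trained) and `history` (data.frame with
#'   columns fold, epoch, loss, train_acc, val_acc; fold 0 is the final
#'   full-data fit).
#' @export
train_classifier <- function(clf, ds, cfg = clf$cfg) {
  stopifnot(inherits(clf, "task_classifier"), inherits(ds, "labeled_dataset"))
  if (!length(ds$maps)) stop("cannot train on an empty dataset")
  labels <- ds_labels(ds)
  if (anyNA(labels)) stop("all training maps must be labeled")
  if (length(unique(labels)) < 2L)
    stop("single-class dataset: training requires at least two classes")
  rows <- list()
  if (cfg$folds >= 2L) {
    fold <- stratified_folds(labels, cfg$folds, cfg$seed)
    for (f in seq_len(cfg$folds)) {
      tr_i <- which(fold != f); va_i <- which(fold == f)
      if (!length(va_i)) next
      set.seed(cfg$seed + f)
      fclf <- build_classifier(clf$cfg, clf$input_shape)
      set.seed(cfg$seed + 1000L + f)
      fit <- clf_fit_epochs(fclf, ds$maps[tr_i], labels[tr_i], cfg, cfg$epochs,
        eval_fun = function(m, ep) {
          tr <- clf_ce_and_acc(m, ds$maps[tr_i], labels[tr_i])
          va <- clf_ce_and_acc(m, ds$maps[va_i], labels[va_i])
          data.frame(fold = f, epoch = ep, loss = tr$loss,
                     train_acc = tr$acc, val_acc = va$acc)
        })
      rows <- c(rows, fit$history)
    }
  }
  set.seed(cfg$seed)
  final <- build_classifier(clf$cfg, clf$input_shape)
  set.seed(cfg$seed + 999L)
  fit <- clf_fit_epochs(final, ds$maps, labels, cfg, cfg$epochs,
    eval_fun = function(m, ep) {
      tr <- clf_ce_and_acc(m, ds$maps, labels)
      data.frame(fold = 0L, epoch = ep, loss = tr$loss,
                 train_acc = tr$acc, val_acc = NA_real_)
    })
  out <- fit$clf
  out$trained <- TRUE
  list(classifier = out, history = do.call(rbind, c(rows, fit$history)))
}

#' Confusion matrix of a classifier on a labeled dataset
#'
#' @param clf A `task_classifier`, or a function mapping a list of maps to
#'   0-based class assignments (useful for reference predictors).
#' @param ds A [labeled_dataset]; every map must be labeled.
#' @return K x K integer matrix (rows true class, columns assigned class) with
#'   class-name dimnames and an `accuracy` attribute.
#' @export
evaluate_confusion <- function(clf, ds) {
  stopifnot(inherits(ds, "labeled_dataset"), length(ds$maps) > 0)
  labels <- ds_labels(ds)
  if (anyNA(labels)) stop("unlabeled map present; confusion matrix needs labels")
  pred <- if (is.function(clf)) clf(ds$maps) else predict(clf, ds)$class
  K <- length(ds$class_names)
  cm <- matrix(0L, K, K, dimnames = list(true = ds$class_names,
                                         assigned = ds$class_names))
  for (i in seq_along(labels)) {
    cm[labels[i] + 1L, pred[i] + 1L] <- cm[labels[i] + 1L, pred[i] + 1L] + 1L
  }
  attr(cm, "accuracy") <- sum(diag(cm)) / sum(cm)
  cm
}

#' Save / load a task classifier checkpoint
#'
#' Self-describing single-file text checkpoint (config + parameters).
#'
#' @param clf A `task_classifier`.
#' @param path File path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(clf, path) {
  meta <- list(kind = "task_classifier",
               cfg = unclass(clf$cfg), input_shape = clf$input_shape,
               trained = clf$trained)
  meta$cfg$conv_blocks <- lapply(meta$cfg$conv_blocks, as.integer)
  save_params_file(meta, clf$par, path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- load_params_file(path)
  if (!identical(x$meta$kind, "task_classifier")) stop("not a classifier checkpoint")
  cfgl <- x$meta$cfg
  cfg <- classifier_config(conv_blocks = lapply(seq_len(nrow(cfgl$conv_blocks)),
                                                function(i) as.integer(cfgl$conv_blocks[i, ])),
                           fc_widths = cfgl$fc_widths, K = cfgl$K, lr = cfgl$lr,
                           batch_size = cfgl$batch_size, epochs = cfgl$epochs,
                           optimizer = cfgl$optimizer, folds = cfgl$folds,
                           seed = cfgl$seed)
  clf <- build_classifier(cfg, x$meta$input_shape)
  clf$par <- x$par
  clf$trained <- isTRUE(x$meta$trained)
  clf
}
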