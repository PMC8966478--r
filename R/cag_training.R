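# Loss terms and the WGAN-GP training loop that turns a generator into a
# counterfactual activation generator (CAG) against a frozen task classifier.
#
# Objectives (lambda_* are loss weights):
#   critic      minimizes  -(Lwass_r - Lwass_f) + lambda_gp*Lgp + lambda_cls*Lcls_r
#   generator   minimizes  -E[D_src(fake)] + lambda_cls*Lcls_f
#                          + lambda_rec*Lrec + lambda_cnn*Lcnn
# i.e. the critic pushes real scores up and fake scores down, the generator
# chases realness, target-class domain probability, cycle-consistent
# reconstruction, and the frozen classifier's assignment of the target class.

#' Loss weights for CAG training
#'
#' Defaults are the published setting: gradient penalty 10, domain
#' classification 1, cycle reconstruction 10, classifier guidance 1.
#'
#' @param lambda_gp,lambda_cls,lambda_rec,lambda_cnn Nonnegative weights.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_gp = 10, lambda_cls = 1, lambda_rec = 10,
                         lambda_cnn = 1) {
  stopifnot(lambda_gp >= 0, lambda_cls >= 0, lambda_rec >= 0, lambda_cnn >= 0)
  structure(list(lambda_gp = lambda_gp, lambda_cls = lambda_cls,
                 lambda_rec = lambda_rec, lambda_cnn = lambda_cnn),
            class = "loss_weights")
}

#' Training configuration for the CAG
#'
#' Published settings: batch size 16, learning rate 1e-4, Adam with beta1 =
#' 0.5 and beta2 = 0.999, five critic updates per generator update, 10,000
#' epochs.  The desk-scale default trains for `gen_steps` generator updates
#' instead; if `epochs` is given it is converted at
#' `ceiling(n / batch_size)` generator steps per epoch.
#'
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate for both networks.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param gen_steps Number of generator updates (desk-scale default 300).
#' @param epochs Optional full-pass count overriding `gen_steps`.
#' @param critic_steps_per_gen_step Critic updates per generator update.
#' @param gen_base_ch,disc_base_ch Network widths.
#' @param checkpoint_every Keep a parameter snapshot every this many
#'   generator steps (divergence fallback).
#' @param seed Global seed for initialization, batch order, target sampling
#'   and gradient-penalty interpolation.
#' @return A `cag_train_config`.
#' @export
cag_train_config <- function(batch_size = 16L, lr = 1e-4, adam_beta1 = 0.5,
                             adam_beta2 = 0.999, gen_steps = 300L,
                             epochs = NULL, critic_steps_per_gen_step = 5L,
                             gen_base_ch = 8L, disc_base_ch = 16L,
                             checkpoint_every = 50L, seed = 1L) {
  stopifnot(batch_size >= 1, lr > 0, gen_steps >= 1,
            critic_steps_per_gen_step >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 gen_steps = as.integer(gen_steps), epochs = epochs,
                 critic_steps_per_gen_step = as.integer(critic_steps_per_gen_step),
                 gen_base_ch = as.integer(gen_base_ch),
                 disc_base_ch = as.integer(disc_base_ch),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "cag_train_config")
}

# --- standalone loss operations (numeric; accept toy critics/generators) ---

#' Wasserstein loss terms
#'
#' `Lwass_r` is the mean critic realness score over real maps, `Lwass_f` over
#' generated maps, and `Lwass = Lwass_r - Lwass_f`.
#'
#' @param disc A `cag_discriminator`, [linear_critic], or a function mapping
#'   a list of maps to numeric scores.
#' @param real_maps,fake_maps Nonempty lists of [activation_map]s.
#' @return List with `lwass_r`, `lwass_f`, `lwass`.
#' @export
wasserstein_terms <- function(disc, real_maps, fake_maps) {
  if (!length(real_maps) || !length(fake_maps)) stop("empty batch")
  lr <- mean(disc_scores(disc, real_maps))
  lf <- mean(disc_scores(disc, fake_maps))
  list(lwass_r = lr, lwass_f = lf, lwass = lr - lf)
}

# Build the gradient-penalty node for interpolates; pn must be leaves when
# the penalty participates in a parameter update (second-order path).
gp_node <- function(disc, pn, real_arr, fake_arr, B, t) {
  texp <- array(rep(t, each = length(real_arr) / B), dim(real_arr))
  xhat <- ad_leaf(texp * real_arr + (1 - texp) * fake_arr)
  src <- disc_src_node(disc, pn, xhat, B)
  g <- ad_grad(ad_sum(src), list(xhat))[[1]]
  D <- length(real_arr) / B
  g2 <- ad_reshape(ad_mul(g, g), c(D, B))
  nrm <- ad_sqrt(ad_add(ad_matmul(ad_const(matrix(1, 1, D)), g2), 1e-12))
  dev <- ad_sub(nrm, 1)
  ad_mean(ad_mul(dev, dev))
}

#' WGAN gradient penalty
#'
#' For each real/fake pair an interpolate `xhat = t*real + (1-t)*fake` with
#' `t ~ U(0,1)` is drawn; the penalty is the batch mean of
#' `(||grad_xhat D_src(xhat)||_2 - 1)^2`.
#'
#' @inheritParams wasserstein_terms
#' @param t Optional fixed interpolation coefficients (length B), mainly for
#'   testing; default draws from the current RNG.
#' @return Scalar penalty value.
#' @export
gradient_penalty <- function(disc, real_maps, fake_maps, t = NULL) {
  B <- length(real_maps)
  stopifnot(B > 0, length(fake_maps) == B)
  real_arr <- maps_to_array(real_maps)
  fake_arr <- maps_to_array(fake_maps)
  if (is.null(t)) t <- runif(B)
  pn <- if (inherits(disc, "cag_discriminator")) params_as_consts(disc$par)
        else NULL
  ad_value(gp_node(disc, pn, real_arr, fake_arr, B, t))
}

domain_nll <- function(probs, labels0, eps = 1e-12) {
  pt <- probs[cbind(as.integer(labels0) + 1L, seq_len(ncol(probs)))]
  -mean(log(pmax(pt, eps)))
}

#' Domain classification loss on real maps
#'
#' Mean negative log probability that the discriminator's domain head assigns
#' to each map's true class (probabilities floored at 1e-12).
#'
#' @param disc A `cag_discriminator` or a function mapping a list of maps to
#'   a K x B probability matrix.
#' @param maps Nonempty list of [activation_map]s.
#' @param labels 0-based true class per map.
#' @return Scalar loss.
#' @export
domain_loss_real <- function(disc, maps, labels) {
  if (!length(maps)) stop("empty batch")
  domain_nll(disc_domain_probs(disc, maps), labels)
}

#' Domain classification loss on generated maps
#'
#' The same negative log probability, evaluated on `gen`-translated maps
#' against their target labels.
#'
#' @inheritParams domain_loss_real
#' @param gen A `cag_generator` or a toy function `(maps, targets) -> maps`.
#' @param targets 0-based target class per map.
#' @return Scalar loss.
#' @export
domain_loss_fake <- function(disc, gen, maps, targets) {
  fakes <- cag_translate(gen, maps, targets)
  domain_loss_real(disc, fakes, targets)
}

#' Cycle-consistency reconstruction loss
#'
#' Translates each map to its target class and back to its original class and
#' returns the batch mean of the per-pixel mean absolute difference (computed
#' over within-mask pixels).
#'
#' @param gen A `cag_generator` or toy function `(maps, targets) -> maps`.
#' @param maps Nonempty list of [activation_map]s.
#' @param targets 0-based target classes for the forward translation.
#' @param orig_labels 0-based classes for the return translation (defaults to
#'   each map's label).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(gen, maps, targets, orig_labels = NULL) {
  if (!length(maps)) stop("empty batch")
  if (is.null(orig_labels)) orig_labels <- vapply(maps, function(m) m$label, integer(1))
  fakes <- cag_translate(gen, maps, targets)
  recon <- cag_translate(gen, fakes, orig_labels)
  mask <- maps[[1]]$mask
  mean(vapply(seq_along(maps), function(i)
    mean(abs(maps[[i]]$values[mask] - recon[[i]]$values[mask])), numeric(1)))
}

#' Classifier guidance loss
#'
#' Mean negative log probability the frozen task classifier assigns to each
#' generated map's target class; gradients flow to the generator only.
#'
#' @param clf A `task_classifier` or a function mapping a list of maps to a
#'   K x B probability matrix.
#' @param fake_maps Nonempty list of generated [activation_map]s.
#' @param targets 0-based target class per map.
#' @return Scalar loss.
#' @export
classifier_guidance_loss <- function(clf, fake_maps, targets) {
  if (!length(fake_maps)) stop("empty batch")
  probs <- if (is.function(clf)) clf(fake_maps) else predict(clf, fake_maps)$probs
  domain_nll(probs, targets)
}

# --- training state and steps ----------------------------------------------

#' Initialize a CAG training state
#'
#' @param clf Trained `task_classifier` (frozen throughout).
#' @param ds Nonempty [labeled_dataset] (the classifier's training split).
#' @param weights A [loss_weights].
#' @param cfg A [cag_train_config].
#' @param gen,disc Optional pre-built networks (defaults built from `cfg`).
#' @return A `cag_state` environment.
#' @export
cag_init_state <- function(clf, ds, weights = loss_weights(),
                           cfg = cag_train_config(), gen = NULL, disc = NULL) {
  stopifnot(inherits(clf, "task_classifier"), length(ds$maps) > 0)
  d <- dim(ds$maps[[1]]$values)
  K <- length(ds$class_names)
  if (is.null(gen)) gen <- build_generator(K, d[1], d[2], cfg$gen_base_ch, cfg$seed)
  if (is.null(disc)) disc <- build_discriminator(K, d[1], d[2], cfg$disc_base_ch,
                                                 cfg$seed + 1L)
  st <- new.env(parent = emptyenv())
  st$clf <- clf; st$gen <- gen; st$disc <- disc
  st$weights <- weights; st$cfg <- cfg
  st$mask <- ds_mask(ds)
  st$data <- maps_to_array(ds$maps)
  st$labels <- ds_labels(ds)
  st$n <- length(ds$maps); st$K <- K
  st$opt_g <- adam_init(gen$par)
  st$opt_d <- adam_init(disc$par)
  st$step <- 0L
  class(st) <- c("cag_state", class(st))
  st
}

sample_batch <- function(st) {
  B <- min(st$cfg$batch_size, st$n)
  idx <- sample.int(st$n, B)
  targets <- sample.int(st$K, B, replace = TRUE) - 1L
  list(idx = idx, targets = targets, B = B,
       arr = st$data[, , , idx, drop = FALSE], labels = st$labels[idx])
}

check_finite <- function(report, what) {
  bad <- !vapply(report, function(v) all(is.finite(v)), logical(1))
  if (any(bad))
    stop("non-finite ", what, " loss component(s): ",
         paste(names(report)[bad], collapse = ", "))
}

#' One critic (discriminator) update
#'
#' Performs a single Adam step on the discriminator; generator and classifier
#' parameters are untouched.
#'
#' @param st A `cag_state`.
#' @param batch Optional batch (as from the internal sampler); default drawn
#'   from the state RNG.
#' @return Named list of loss components for this step.
#' @export
discriminator_step <- function(st, batch = NULL) {
  if (is.null(batch)) batch <- sample_batch(st)
  B <- batch$B
  fake_arr <- gen_translate_array(st$gen, batch$arr, batch$targets, st$mask)
  pn <- params_as_leaves(st$disc$par)
  out_r <- disc_forward(st$disc, pn, ad_const(batch$arr), B)
  out_f <- disc_forward(st$disc, pn, ad_const(fake_arr), B)
  lwass_r <- ad_mean(out_r$src)
  lwass_f <- ad_mean(out_f$src)
  lgp <- gp_node(st$disc, pn, batch$arr, fake_arr, B, runif(B))
  lcls_r <- nll_cols(out_r$cls, batch$labels, st$K, B)
  obj <- ad_add(ad_add(ad_sub(lwass_f, lwass_r),
                       ad_mul(lgp, st$weights$lambda_gp)),
                ad_mul(lcls_r, st$weights$lambda_cls))
  gr <- ad_grad(obj, pn)
  gv <- lapply(gr, ad_value); names(gv) <- names(st$disc$par)
  report <- list(lwass_r = ad_value(lwass_r), lwass_f = ad_value(lwass_f),
                 lgp = ad_value(lgp), lcls_r = ad_value(lcls_r),
                 ld = ad_value(obj))
  check_finite(report, "discriminator")
  upd <- adam_step(st$disc$par, gv, st$opt_d, st$cfg$lr,
                   st$cfg$adam_beta1, st$cfg$adam_beta2)
  st$disc$par <- upd$par; st$opt_d <- upd$st
  report
}

# Conditioned stack with a differentiable image channel: the generated image
# is scattered into channel 1 of a (K+1, H, W, B) layout and the constant
# one-hot label channels are added.
concat_condition_node <- function(img_node, targets, K, H, W, B) {
  key <- plan_key("cond", K, H, W, B)
  idx <- .ad$plans[[key]]
  if (is.null(idx)) {
    pos <- seq_len(H * W * B) - 1L
    idx <- 1L + (K + 1L) * pos
    .ad$plans[[key]] <- idx
  }
  lab <- condition_input(array(0, c(1L, H, W, B)), targets, K)
  ad_add(ad_scatter(img_node, idx, (K + 1L) * H * W * B,
                    dims = c(K + 1L, H, W, B)),
         ad_const(lab))
}

#' One generator update
#'
#' Performs a single Adam step on the generator against the frozen critic and
#' classifier; discriminator and classifier parameters are untouched.
#'
#' @inheritParams discriminator_step
#' @return Named list of loss components for this step (`lg` follows the
#'   printed total `Lwass + lambda_cls*Lcls_f + lambda_rec*Lrec +
#'   lambda_cnn*Lcnn`).
#' @export
generator_step <- function(st, batch = NULL) {
  if (is.null(batch)) batch <- sample_batch(st)
  B <- batch$B
  gen <- st$gen; H <- gen$H; W <- gen$W; K <- st$K
  pn_g <- params_as_leaves(gen$par)
  pn_d <- params_as_consts(st$disc$par)
  pn_c <- params_as_consts(st$clf$par)
  mnode <- mask_node_for(st$mask, B)
  x_cond <- ad_const(condition_input(batch$arr, batch$targets, K))
  fake <- gen_forward(gen, pn_g, x_cond, mnode, B)
  d_f <- disc_forward(st$disc, pn_d, fake, B)
  lwass_f <- ad_mean(d_f$src)
  lcls_f <- nll_cols(d_f$cls, batch$targets, K, B)
  cond_back <- concat_condition_node(fake, batch$labels, K, H, W, B)
  recon <- gen_forward(gen, pn_g, cond_back, mnode, B)
  mexp <- array(rep(as.numeric(st$mask), B), c(1L, H, W, B))
  nmask <- sum(st$mask)
  lrec <- ad_mul(ad_sum(ad_mul(ad_abs(ad_sub(ad_const(batch$arr), recon)),
                               ad_const(mexp))), 1 / (B * nmask))
  p_f <- clf_forward(st$clf, pn_c, fake, B)
  lcnn <- nll_cols(p_f, batch$targets, K, B)
  obj <- ad_add(ad_add(ad_neg(lwass_f), ad_mul(lcls_f, st$weights$lambda_cls)),
                ad_add(ad_mul(lrec, st$weights$lambda_rec),
                       ad_mul(lcnn, st$weights$lambda_cnn)))
  gr <- ad_grad(obj, pn_g)
  gv <- lapply(gr, ad_value); names(gv) <- names(gen$par)
  lwass_r_val <- mean(as.numeric(ad_value(
    disc_forward(st$disc, pn_d, ad_const(batch$arr), B)$src)))
  report <- list(lwass_r = lwass_r_val, lwass_f = ad_value(lwass_f),
                 lcls_f = ad_value(lcls_f), lrec = ad_value(lrec),
                 lcnn = ad_value(lcnn),
                 lg = (lwass_r_val - ad_value(lwass_f)) +
                   st$weights$lambda_cls * ad_value(lcls_f) +
                   st$weights$lambda_rec * ad_value(lrec) +
                   st$weights$lambda_cnn * ad_value(lcnn))
  check_finite(report, "generator")
  upd <- adam_step(gen$par, gv, st$opt_g, st$cfg$lr,
                   st$cfg$adam_beta1, st$cfg$adam_beta2)
  st$gen$par <- upd$par; st$opt_g <- upd$st
  report
}

#' Train a counterfactual activation generator
#'
#' Alternates `critic_steps_per_gen_step` discriminator updates with one
#' generator update, sampling target classes uniformly, for
#' `cfg$gen_steps` generator updates (or `cfg$epochs` full passes).  The task
#' classifier stays frozen.  If a loss turns non-finite the loop halts and
#' returns the last checkpointed parameters with `diverged = TRUE`.
#'
#' @param clf Trained `task_classifier`.
#' @param ds Training [labeled_dataset].
#' @param weights A [loss_weights].
#' @param cfg A [cag_train_config].
#' @param gen,disc Optional pre-built networks.
#' @param verbose Print progress every 50 generator steps.
#' @return List with `gen`, `disc`, `history` (one row per generator step
#'   with all loss components) and `diverged`.
#' @export
train_cag <- function(clf, ds, weights = loss_weights(),
                      cfg = cag_train_config(), gen = NULL, disc = NULL,
                      verbose = FALSE) {
  set.seed(cfg$seed)
  st <- cag_init_state(clf, ds, weights, cfg, gen, disc)
  steps <- cfg$gen_steps
  if (!is.null(cfg$epochs))
    steps <- as.integer(cfg$epochs * ceiling(st$n / cfg$batch_size))
  hist <- vector("list", steps)
  ckpt <- list(gen = st$gen$par, disc = st$disc$par, step = 0L)
  diverged <- FALSE
  for (s in seq_len(steps)) {
    rep_d <- NULL; rep_g <- NULL
    ok <- tryCatch({
      for (j in seq_len(cfg$critic_steps_per_gen_step))
        rep_d <- discriminator_step(st)
      rep_g <- generator_step(st)
      TRUE
    }, error = function(e) {
      if (grepl("non-finite", conditionMessage(e))) FALSE else stop(e)
    })
    if (!ok) {
      warning("training diverged at generator step ", s,
              "; restoring checkpoint from step ", ckpt$step)
      st$gen$par <- ckpt$gen; st$disc$par <- ckpt$disc
      diverged <- TRUE
      hist <- hist[seq_len(s - 1L)]
      break
    }
    st$step <- s
    hist[[s]] <- data.frame(step = s, lwass_r = rep_g$lwass_r,
                            lwass_f = rep_g$lwass_f, lgp = rep_d$lgp,
                            lcls_r = rep_d$lcls_r, lcls_f = rep_g$lcls_f,
                            lrec = rep_g$lrec, lcnn = rep_g$lcnn,
                            ld = rep_d$ld, lg = rep_g$lg)
    if (s %% cfg$checkpoint_every == 0L)
      ckpt <- list(gen = st$gen$par, disc = st$disc$par, step = s)
    if (verbose && s %% 50L == 0L)
      message(sprintf("step %d/%d  LG %.3f  LD %.3f  Lrec %.4f  Lcnn %.3f",
                      s, steps, hist[[s]]$lg, hist[[s]]$ld, hist[[s]]$lrec,
                      hist[[s]]$lcnn))
  }
  list(gen = st$gen, disc = st$disc, history = do.call(rbind, hist),
       diverged = diverged)
}
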