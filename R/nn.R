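# Convolutional building blocks on the autodiff engine.
#
# Tensor layout convention: a batch of feature maps is a flat numeric array
# with dim c(C, H, W, B) (channel fastest).  Convolution is im2col + matmul;
# the im2col index is precomputed once per (shape, kernel) and cached, so the
# per-step cost is one gather and one BLAS matmul per layer.

plan_key <- function(...) paste(..., sep = "_")

# im2col plan: index matrix (K x N) into the flat input, 0 = zero padding.
# Column order is (ho, wo, b) with ho fastest, so the (Cout x N) matmul output
# is already a (Cout, Ho, Wo, B) array; row order is (ci, kh, kw).
conv_plan <- function(Cin, H, W, B, k, stride, pad) {
  key <- plan_key("conv", Cin, H, W, B, k, stride, pad)
  p <- .ad$plans[[key]]
  if (!is.null(p)) return(p)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  K <- Cin * k * k
  ci <- rep_len(seq_len(Cin), K)
  dh <- rep(rep(seq_len(k), each = Cin), times = k)
  dw <- rep(seq_len(k), each = Cin * k)
  ho <- rep_len(seq_len(Ho), Ho * Wo * B)
  wo <- rep(rep(seq_len(Wo), each = Ho), times = B)
  b  <- rep(seq_len(B), each = Ho * Wo)
  in_h <- outer(dh, (ho - 1L) * stride, "+") - pad     # K x N
  in_w <- outer(dw, (wo - 1L) * stride, "+") - pad
  ci_m <- matrix(ci, K, length(ho))
  b_m  <- matrix(rep(b, each = K), K, length(ho))
  valid <- in_h >= 1L & in_h <= H & in_w >= 1L & in_w <= W
  idx <- ci_m + Cin * (in_h - 1L) + Cin * H * (in_w - 1L) + Cin * H * W * (b_m - 1L)
  idx[!valid] <- 0L
  p <- list(idx = as.integer(idx), K = K, N = Ho * Wo * B, Ho = Ho, Wo = Wo)
  .ad$plans[[key]] <- p
  p
}

conv2d <- function(x, Wn, bn, Cin, H, W, B, k, stride, pad) {
  pl <- conv_plan(Cin, H, W, B, k, stride, pad)
  Cout <- length(bn$v)
  cols <- ad_gather(x, pl$idx, dims = c(pl$K, pl$N))
  out <- ad_matmul(Wn, cols)
  bexp <- ad_gather(bn, rep_len(seq_len(Cout), Cout * pl$N), dims = c(Cout, pl$N))
  out <- ad_add(out, bexp)
  ad_reshape(out, c(Cout, pl$Ho, pl$Wo, B))
}

# Zero-insertion 2x upsampling; a following stride-1 convolution makes the
# pair equivalent to a stride-2 transposed convolution.
upsample2 <- function(x, C, H, W, B) {
  key <- plan_key("up2", C, H, W, B)
  idx <- .ad$plans[[key]]
  if (is.null(idx)) {
    Ho <- 2L * H; Wo <- 2L * W
    c_ <- rep_len(seq_len(C), C * Ho * Wo * B)
    h_ <- rep(rep(seq_len(Ho), each = C), times = Wo * B)
    w_ <- rep(rep(seq_len(Wo), each = C * Ho), times = B)
    b_ <- rep(seq_len(B), each = C * Ho * Wo)
    odd <- (h_ %% 2L == 1L) & (w_ %% 2L == 1L)
    idx <- c_ + C * ((h_ + 1L) %/% 2L - 1L) + C * H * ((w_ + 1L) %/% 2L - 1L) +
      C * H * W * (b_ - 1L)
    idx[!odd] <- 0L
    .ad$plans[[key]] <- idx
  }
  ad_gather(x, idx, dims = c(C, 2L * H, 2L * W, B))
}

# Spatial zero-pad (dh, dw added at bottom/right) and its inverse crop.
pad_hw <- function(x, C, H, W, B, Ht, Wt) {
  if (Ht == H && Wt == W) return(x)
  key <- plan_key("pad", C, H, W, B, Ht, Wt)
  idx <- .ad$plans[[key]]
  if (is.null(idx)) {
    c_ <- rep_len(seq_len(C), C * Ht * Wt * B)
    h_ <- rep(rep(seq_len(Ht), each = C), times = Wt * B)
    w_ <- rep(rep(seq_len(Wt), each = C * Ht), times = B)
    b_ <- rep(seq_len(B), each = C * Ht * Wt)
    inside <- h_ <= H & w_ <= W
    idx <- c_ + C * (h_ - 1L) + C * H * (w_ - 1L) + C * H * W * (b_ - 1L)
    idx[!inside] <- 0L
    .ad$plans[[key]] <- idx
  }
  ad_gather(x, idx, dims = c(C, Ht, Wt, B))
}

crop_hw <- function(x, C, H, W, B, Ht, Wt) {
  if (Ht == H && Wt == W) return(x)
  key <- plan_key("crop", C, H, W, B, Ht, Wt)
  idx <- .ad$plans[[key]]
  if (is.null(idx)) {
    c_ <- rep_len(seq_len(C), C * Ht * Wt * B)
    h_ <- rep(rep(seq_len(Ht), each = C), times = Wt * B)
    w_ <- rep(rep(seq_len(Wt), each = C * Ht), times = B)
    b_ <- rep(seq_len(B), each = C * Ht * Wt)
    idx <- c_ + C * (h_ - 1L) + C * H * (w_ - 1L) + C * H * W * (b_ - 1L)
    .ad$plans[[key]] <- idx
  }
  ad_gather(x, idx, dims = c(C, Ht, Wt, B))
}

instance_norm <- function(x, gamma, beta, C, H, W, B, eps = 1e-5) {
  HW <- H * W
  key <- plan_key("in", C, HW, B)
  gi <- .ad$plans[[key]]
  if (is.null(gi)) {
    base <- rep_len(seq_len(C), C * HW)
    gi <- list(
      idx_g = as.integer(rep(base, times = B) + C * rep(0:(B - 1L), each = C * HW)),
      idx_c = rep_len(seq_len(C), C * HW * B))
    .ad$plans[[key]] <- gi
  }
  dims <- c(C, H, W, B)
  mu <- ad_mul(ad_scatter(x, gi$idx_g, C * B), 1 / HW)
  xc <- ad_sub(x, ad_gather(mu, gi$idx_g, dims = dims))
  va <- ad_mul(ad_scatter(ad_mul(xc, xc), gi$idx_g, C * B), 1 / HW)
  dinv <- ad_recip(ad_sqrt(ad_add(va, eps)))
  xn <- ad_mul(xc, ad_gather(dinv, gi$idx_g, dims = dims))
  ad_add(ad_mul(xn, ad_gather(gamma, gi$idx_c, dims = dims)),
         ad_gather(beta, gi$idx_c, dims = dims))
}

dense <- function(x, Wn, bn, B) {
  Dout <- length(bn$v)
  out <- ad_matmul(Wn, x)
  ad_add(out, ad_gather(bn, rep_len(seq_len(Dout), Dout * B), dims = c(Dout, B)))
}

# Column-wise softmax of a (K, B) logit matrix; the per-column max used for
# stabilization is a detached constant (its gradient contribution is zero).
softmax_cols <- function(z, K, B) {
  zm <- matrix(z$v, K, B)
  m <- apply(zm, 2L, max)
  colidx <- rep(seq_len(B), each = K)
  z2 <- ad_sub(z, ad_gather(ad_const(m), colidx, dims = c(K, B)))
  e <- ad_exp(z2)
  s <- ad_scatter(e, colidx, B)
  ad_mul(e, ad_gather(ad_recip(s), colidx, dims = c(K, B)))
}

# Mean negative log probability of the true class; probabilities are floored
# at `eps` before the logarithm.
nll_cols <- function(p, labels0, K, B, eps = 1e-12) {
  sel <- as.integer(labels0 + 1L + K * (0:(B - 1L)))
  pt <- ad_gather(p, sel)
  ad_neg(ad_mean(ad_log(ad_clamp_min(pt, eps))))
}

# --- parameter initialization and optimizers -------------------------------

he_conv <- function(Cout, Cin, k) {
  sd <- sqrt(2 / (Cin * k * k))
  matrix(rnorm(Cout * Cin * k * k, sd = sd), Cout, Cin * k * k)
}

he_dense <- function(Dout, Din) {
  matrix(rnorm(Dout * Din, sd = sqrt(2 / Din)), Dout, Din)
}

params_as_leaves <- function(par) lapply(par, ad_leaf)
params_as_consts <- function(par) lapply(par, ad_const)

sgd_step_params <- function(par, grads, lr) {
  for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * grads[[nm]]
  par
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) { z <- p; z[] <- 0; z }),
       v = lapply(par, function(p) { z <- p; z[] <- 0; z }),
       t = 0L)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, st = st)
}
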