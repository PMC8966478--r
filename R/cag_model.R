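# Conditional generator (CAG) and discriminator for multi-domain translation
# of masked activation maps, in the StarGAN mold: one generator handles all
# K classes, conditioned by tiling a one-hot target label into K constant
# image channels; one discriminator emits an unbounded realness score (mean
# of a patch-score map) and a K-class domain probability head.

#' Condition an activation image on a target class
#'
#' Expands a one-hot target label into K constant channels of the image size
#' and concatenates them to the grayscale channel, giving the K+1-channel
#' generator input.
#'
#' @param map An [activation_map], or a `(1, H, W, B)` numeric array.
#' @param target 0-based target class index (length 1 or B).
#' @param K Number of classes.
#' @return A `(K+1, H, W, B)` numeric array.
#' @export
condition_input <- function(map, target, K) {
  arr <- if (inherits(map, "activation_map"))
    array(map$values, c(1L, dim(map$values), 1L)) else map
  d <- dim(arr); H <- d[2]; W <- d[3]; B <- d[4]
  target <- as.integer(rep_len(target, B))
  if (any(target < 0L | target >= K)) stop("target class out of range 0..K-1")
  out <- array(0, c(K + 1L, H, W, B))
  out[1L, , , ] <- arr[1L, , , ]
  for (b in seq_len(B)) out[1L + target[b] + 1L, , , b] <- 1
  out
}

gen_channels <- function(base_ch) c(base_ch, 2L * base_ch, 4L * base_ch)

#' Build an (untrained) counterfactual activation generator
#'
#' Encoder of three convolution layers (strides 1, 2, 2) with instance
#' normalization and ReLU, two stride-1 bottleneck convolutions, and four
#' upsampling-path convolutions (two zero-insertion x2 upsamplings each
#' followed by a convolution, then two stride-1 convolutions), ending in a
#' sigmoid so outputs live in \[0, 1\].  Inputs are internally zero-padded to
#' the next multiple of 4 and outputs cropped back; the output is multiplied
#' by the brain mask.
#'
#' @param K Number of classes.
#' @param H,W Activation-map size.
#' @param base_ch Channel width of the first layer (doubling per stride).
#' @param seed Seed for deterministic parameter initialization.
#' @return A `cag_generator`.
#' @export
build_generator <- function(K, H, W, base_ch = 8L, seed = 1L) {
  ch <- gen_channels(as.integer(base_ch))
  Ht <- as.integer(4L * ceiling(H / 4)); Wt <- as.integer(4L * ceiling(W / 4))
  set.seed(seed)
  Cin <- K + 1L
  par <- list()
  specs <- list(
    d1 = c(Cin, ch[1]), d2 = c(ch[1], ch[2]), d3 = c(ch[2], ch[3]),
    b1 = c(ch[3], ch[3]), b2 = c(ch[3], ch[3]),
    u1 = c(ch[3], ch[2]), u2 = c(ch[2], ch[1]),
    u3 = c(ch[1], ch[1]), u4 = c(ch[1], 1L))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    par[[paste0(nm, "_W")]] <- he_conv(s[2], s[1], 3L)
    par[[paste0(nm, "_b")]] <- numeric(s[2])
    if (nm != "u4") {
      par[[paste0(nm, "_g")]] <- rep(1, s[2])
      par[[paste0(nm, "_be")]] <- numeric(s[2])
    }
  }
  structure(list(K = as.integer(K), H = as.integer(H), W = as.integer(W),
                 Ht = Ht, Wt = Wt, ch = ch, par = par, seed = as.integer(seed)),
            class = "cag_generator")
}

gen_block <- function(x, pn, nm, Cin, H, W, B, stride) {
  Cout <- length(pn[[paste0(nm, "_b")]]$v)
  h <- conv2d(x, pn[[paste0(nm, "_W")]], pn[[paste0(nm, "_b")]],
              Cin, H, W, B, 3L, stride, 1L)
  Ho <- (H + 2L - 3L) %/% stride + 1L
  Wo <- (W + 2L - 3L) %/% stride + 1L
  h <- instance_norm(h, pn[[paste0(nm, "_g")]], pn[[paste0(nm, "_be")]],
                     Cout, Ho, Wo, B)
  ad_relu(h)
}

# Forward pass: x is a (K+1, H, W, B) adnode, mask_node a (1, H, W, B) 0/1
# constant; returns a (1, H, W, B) node with out-of-mask pixels exactly zero.
gen_forward <- function(gen, pn, x, mask_node, B) {
  K <- gen$K; ch <- gen$ch
  Ht <- gen$Ht; Wt <- gen$Wt
  h <- pad_hw(x, K + 1L, gen$H, gen$W, B, Ht, Wt)
  h <- gen_block(h, pn, "d1", K + 1L, Ht, Wt, B, 1L)
  h <- gen_block(h, pn, "d2", ch[1], Ht, Wt, B, 2L)
  h2 <- Ht %/% 2L; w2 <- Wt %/% 2L
  h <- gen_block(h, pn, "d3", ch[2], h2, w2, B, 2L)
  h4 <- h2 %/% 2L; w4 <- w2 %/% 2L
  h <- gen_block(h, pn, "b1", ch[3], h4, w4, B, 1L)
  h <- gen_block(h, pn, "b2", ch[3], h4, w4, B, 1L)
  h <- upsample2(h, ch[3], h4, w4, B)
  h <- gen_block(h, pn, "u1", ch[3], h2, w2, B, 1L)
  h <- upsample2(h, ch[2], h2, w2, B)
  h <- gen_block(h, pn, "u2", ch[2], Ht, Wt, B, 1L)
  h <- gen_block(h, pn, "u3", ch[1], Ht, Wt, B, 1L)
  h <- conv2d(h, pn[["u4_W"]], pn[["u4_b"]], ch[1], Ht, Wt, B, 3L, 1L, 1L)
  h <- ad_sigmoid(h)
  h <- crop_hw(h, 1L, Ht, Wt, B, gen$H, gen$W)
  ad_mul(h, mask_node)
}

mask_node_for <- function(mask, B) {
  ad_const(array(rep(as.numeric(mask), B), c(1L, nrow(mask), ncol(mask), B)))
}

# Numeric batch translation: values (1,H,W,B) array + per-sample targets.
gen_translate_array <- function(gen, arr, targets, mask) {
  B <- dim(arr)[4]
  x <- condition_input(arr, targets, gen$K)
  out <- gen_forward(gen, params_as_consts(gen$par), ad_const(x),
                     mask_node_for(mask, B), B)
  array(ad_value(out), dim(arr))
}

#' Translate an activation map toward a target class
#'
#' Applies the generator to the map conditioned on `target`.  The result has
#' the same shape and mask, values in \[0, 1\], out-of-mask pixels zero, and
#' is deterministic given the generator parameters.
#'
#' @param gen A `cag_generator`.
#' @param map An [activation_map].
#' @param target 0-based target class.
#' @return The counterfactual [activation_map] (label set to `target`).
#' @export
generate_counterfactual <- function(gen, map, target) {
  stopifnot(inherits(gen, "cag_generator"), inherits(map, "activation_map"))
  d <- dim(map$values)
  if (d[1] != gen$H || d[2] != gen$W)
    stop("map shape incompatible with generator (", gen$H, "x", gen$W, ")")
  arr <- array(map$values, c(1L, d, 1L))
  out <- gen_translate_array(gen, arr, target, map$mask)
  activation_map(matrix(out[1, , , 1], d[1], d[2]), map$mask,
                 label = as.integer(target), id = paste0(map$id, "_cf", target))
}

# Generic translation used by the loss operations, so toy generators
# (plain functions maps -> maps) can stand in for a trained network.
cag_translate <- function(gen, maps, targets, mask = NULL) {
  if (is.function(gen)) return(gen(maps, targets))
  if (is.null(mask)) mask <- maps[[1]]$mask
  arr <- maps_to_array(maps)
  out <- gen_translate_array(gen, arr, targets, mask)
  array_to_maps(out, mask, labels = as.integer(rep_len(targets, dim(arr)[4])))
}

#' Build an (untrained) discriminator
#'
#' Three stride-2 convolutions with leaky-ReLU and no normalization, a
#' patch-score realness head (1-channel convolution whose per-sample mean is
#' the realness score) and a domain head (global average pooling into a
#' K-class softmax).
#'
#' @param K Number of classes.
#' @param H,W Activation-map size.
#' @param base_ch Channel width of the first layer.
#' @param seed Seed for deterministic initialization.
#' @return A `cag_discriminator`.
#' @export
build_discriminator <- function(K, H, W, base_ch = 16L, seed = 1L) {
  ch <- c(base_ch, 2L * base_ch, 4L * base_ch)
  set.seed(seed)
  par <- list(
    c1_W = he_conv(ch[1], 1L, 4L), c1_b = numeric(ch[1]),
    c2_W = he_conv(ch[2], ch[1], 4L), c2_b = numeric(ch[2]),
    c3_W = he_conv(ch[3], ch[2], 4L), c3_b = numeric(ch[3]),
    src_W = he_conv(1L, ch[3], 3L), src_b = numeric(1L),
    cls_W = he_dense(K, ch[3]), cls_b = numeric(K))
  dims <- list(H = as.integer(H), W = as.integer(W))
  h1 <- (H + 2L - 4L) %/% 2L + 1L; w1 <- (W + 2L - 4L) %/% 2L + 1L
  h2 <- (h1 + 2L - 4L) %/% 2L + 1L; w2 <- (w1 + 2L - 4L) %/% 2L + 1L
  h3 <- (h2 + 2L - 4L) %/% 2L + 1L; w3 <- (w2 + 2L - 4L) %/% 2L + 1L
  structure(list(K = as.integer(K), H = dims$H, W = dims$W, ch = ch,
                 hs = c(h1, h2, h3), ws = c(w1, w2, w3), par = par,
                 seed = as.integer(seed)),
            class = "cag_discriminator")
}

disc_trunk <- function(disc, pn, x, B) {
  ch <- disc$ch
  h <- ad_lrelu(conv2d(x, pn$c1_W, pn$c1_b, 1L, disc$H, disc$W, B, 4L, 2L, 1L))
  h <- ad_lrelu(conv2d(h, pn$c2_W, pn$c2_b, ch[1], disc$hs[1], disc$ws[1], B, 4L, 2L, 1L))
  ad_lrelu(conv2d(h, pn$c3_W, pn$c3_b, ch[2], disc$hs[2], disc$ws[2], B, 4L, 2L, 1L))
}

disc_forward <- function(disc, pn, x, B) {
  h3 <- disc$hs[3]; w3 <- disc$ws[3]; ch3 <- disc$ch[3]
  h <- disc_trunk(disc, pn, x, B)
  patch <- conv2d(h, pn$src_W, pn$src_b, ch3, h3, w3, B, 3L, 1L, 1L)
  bidx <- rep(seq_len(B), each = h3 * w3)
  src <- ad_mul(ad_scatter(patch, bidx, B), 1 / (h3 * w3))
  gidx <- rep_len(seq_len(ch3), ch3 * h3 * w3 * B) +
    ch3 * rep(0:(B - 1L), each = ch3 * h3 * w3)
  pool <- ad_mul(ad_scatter(h, gidx, ch3 * B), 1 / (h3 * w3))
  pool <- ad_reshape(pool, c(ch3, B))
  logits <- dense(pool, pn$cls_W, pn$cls_b, B)
  list(src = src, cls = softmax_cols(logits, disc$K, B), patch = patch)
}

# Realness-score node for an adnode input; dispatch point that lets simple
# analytic critics (e.g. linear_critic) be used in the loss operations.
disc_src_node <- function(disc, pn, x, B) UseMethod("disc_src_node")

#' @export
disc_src_node.cag_discriminator <- function(disc, pn, x, B)
  disc_forward(disc, pn, x, B)$src

#' Linear critic for analytic checks
#'
#' A realness head `D_src(x) = <w, x> + offset` whose gradient norm is
#' exactly `||w||`; used to validate the gradient-penalty operation.
#'
#' @param w Numeric weight vector/matrix matching the flattened map size.
#' @param offset Scalar offset.
#' @return A `linear_critic`.
#' @export
linear_critic <- function(w, offset = 0) {
  structure(list(w = as.numeric(w), offset = offset), class = "linear_critic")
}

#' @export
disc_src_node.linear_critic <- function(disc, pn, x, B) {
  D <- length(disc$w)
  xm <- ad_reshape(x, c(D, B))
  ad_add(ad_matmul(ad_const(matrix(disc$w, 1L, D)), xm), disc$offset)
}

disc_scores <- function(disc, maps) {
  if (is.function(disc)) return(disc(maps))
  arr <- maps_to_array(maps)
  B <- dim(arr)[4]
  if (inherits(disc, "linear_critic"))
    return(as.numeric(ad_value(disc_src_node(disc, NULL, ad_const(arr), B))))
  as.numeric(ad_value(disc_forward(disc, params_as_consts(disc$par),
                                   ad_const(arr), B)$src))
}

disc_domain_probs <- function(disc, maps) {
  if (is.function(disc)) return(disc(maps))
  arr <- maps_to_array(maps)
  B <- dim(arr)[4]
  matrix(ad_value(disc_forward(disc, params_as_consts(disc$par),
                               ad_const(arr), B)$cls), disc$K, B)
}

#' Discriminator outputs for a batch of maps
#'
#' @param disc A `cag_discriminator`.
#' @param maps A list of [activation_map]s, a [labeled_dataset], or one map.
#' @return List with `realness` (length-B numeric), `domain` (K x B
#'   probability matrix, columns sum to 1) and `patches` (the raw patch-score
#'   array whose per-sample mean equals `realness`).
#' @export
discriminate <- function(disc, maps) {
  stopifnot(inherits(disc, "cag_discriminator"))
  if (inherits(maps, "labeled_dataset")) maps <- maps$maps
  if (inherits(maps, "activation_map")) maps <- list(maps)
  arr <- maps_to_array(maps)
  B <- dim(arr)[4]
  out <- disc_forward(disc, params_as_consts(disc$par), ad_const(arr), B)
  list(realness = as.numeric(ad_value(out$src)),
       domain = matrix(ad_value(out$cls), disc$K, B),
       patches = ad_value(out$patch))
}

#' Save / load generator and discriminator checkpoints
#' @param x A `cag_generator` or `cag_discriminator`.
#' @param path File path.
#' @return `save_cag_net` returns `path` invisibly; `load_cag_net` the object.
#' @export
save_cag_net <- function(x, path) {
  kind <- class(x)[1]
  meta <- list(kind = kind, K = x$K, H = x$H, W = x$W,
               base_ch = x$ch[1], seed = x$seed)
  save_params_file(meta, x$par, path)
}

#' @rdname save_cag_net
#' @export
load_cag_net <- function(path) {
  z <- load_params_file(path)
  m <- z$meta
  obj <- if (identical(m$kind, "cag_generator"))
    build_generator(m$K, m$H, m$W, m$base_ch, m$seed)
  else if (identical(m$kind, "cag_discriminator"))
    build_discriminator(m$K, m$H, m$W, m$base_ch, m$seed)
  else stop("unknown checkpoint kind: ", m$kind)
  obj$par <- z$par
  obj
}
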