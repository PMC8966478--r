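# Reverse-mode automatic differentiation on flat numeric arrays.
#
# Every primitive's backward pass is itself expressed in terms of these same
# primitives, so gradients are ordinary graph nodes and can be differentiated
# again.  This is what makes the WGAN gradient penalty trainable: the penalty
# is a function of an input gradient, and its parameter gradient requires a
# second backward pass through the first.
#
# Values are numeric vectors carrying an optional `dim` attribute; `dim` is
# bookkeeping for matmul/reshape, elementwise ops only check lengths.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L
.ad$plans <- new.env(parent = emptyenv())

ad_node <- function(value, parents = list(), vjp = NULL, req = FALSE) {
  .ad$id <- .ad$id + 1L
  structure(list(v = value, id = .ad$id, parents = parents, vjp = vjp, req = req),
            class = "adnode")
}

#' Create an autodiff leaf (a node gradients are tracked for)
#'
#' @param value Numeric vector or array.
#' @return An `adnode`.
#' @keywords internal
ad_leaf <- function(value) ad_node(value, req = TRUE)

#' Create an autodiff constant (no gradient tracked)
#' @param value Numeric vector or array.
#' @return An `adnode`.
#' @keywords internal
ad_const <- function(value) ad_node(value, req = FALSE)

as_ad <- function(x) if (inherits(x, "adnode")) x else ad_const(x)

#' Extract the numeric value held by a node
#' @param x An `adnode`.
#' @return Numeric vector/array.
#' @keywords internal
ad_value <- function(x) x$v

any_req <- function(parents) {
  for (p in parents) if (p$req) return(TRUE)
  FALSE
}

# Gradient for a possibly scalar-broadcast operand.
.bcast_grad <- function(g, parent_len) {
  if (parent_len == 1L && length(g$v) > 1L) ad_sum(g) else g
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  stopifnot(length(a$v) == length(b$v) || length(a$v) == 1L || length(b$v) == 1L)
  av <- a$v; bv <- b$v
  if (length(av) == length(bv) && !identical(dim(av), dim(bv))) dim(bv) <- dim(av)
  v <- av + bv
  if (is.null(dim(v))) dim(v) <- if (length(av) >= length(bv)) dim(av) else dim(bv)
  la <- length(a$v); lb <- length(b$v)
  ad_node(v, list(a, b), req = any_req(list(a, b)),
          vjp = function(g, node) list(.bcast_grad(g, la), .bcast_grad(g, lb)))
}

ad_neg <- function(a) {
  a <- as_ad(a)
  ad_node(-a$v, list(a), req = a$req, vjp = function(g, node) list(ad_neg(g)))
}

ad_sub <- function(a, b) ad_add(a, ad_neg(as_ad(b)))

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  stopifnot(length(a$v) == length(b$v) || length(a$v) == 1L || length(b$v) == 1L)
  av <- a$v; bv <- b$v
  if (length(av) == length(bv) && !identical(dim(av), dim(bv))) dim(bv) <- dim(av)
  v <- av * bv
  if (is.null(dim(v))) dim(v) <- if (length(av) >= length(bv)) dim(av) else dim(bv)
  la <- length(a$v); lb <- length(b$v)
  ad_node(v, list(a, b), req = any_req(list(a, b)),
          vjp = function(g, node) {
            pa <- node$parents[[1]]; pb <- node$parents[[2]]
            list(.bcast_grad(ad_mul(g, pb), la), .bcast_grad(ad_mul(g, pa), lb))
          })
}

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_ad(a); b <- as_ad(b)
  A <- a$v; B <- b$v
  if (is.null(dim(A))) dim(A) <- c(1L, length(A))
  if (is.null(dim(B))) dim(B) <- c(length(B), 1L)
  v <- if (!ta && !tb) A %*% B
       else if (ta && !tb) crossprod(A, B)
       else if (!ta && tb) tcrossprod(A, B)
       else t(B %*% A)
  ad_node(v, list(a, b), req = any_req(list(a, b)),
          vjp = function(g, node) {
            pa <- node$parents[[1]]; pb <- node$parents[[2]]
            gm <- g
            if (is.null(dim(gm$v))) dim(gm$v) <- dim(node$v)
            ga <- if (ta) ad_matmul(pb, gm, tb, TRUE) else ad_matmul(gm, pb, FALSE, !tb)
            gb <- if (tb) ad_matmul(gm, pa, TRUE, ta) else ad_matmul(pa, gm, !ta, FALSE)
            if (!identical(dim(ga$v), dim(pa$v))) dim(ga$v) <- dim(pa$v)
            if (!identical(dim(gb$v), dim(pb$v))) dim(gb$v) <- dim(pb$v)
            list(ga, gb)
          })
}

ad_reshape <- function(a, dims) {
  a <- as_ad(a)
  stopifnot(prod(dims) == length(a$v))
  v <- a$v; dim(v) <- dims
  ad_node(v, list(a), req = a$req,
          vjp = function(g, node) {
            gd <- g; dim(gd$v) <- dim(node$parents[[1]]$v); list(gd)
          })
}

# Gather: y[i] = x[idx[i]], with idx == 0 meaning "zero fill" (used for padding,
# zero-insertion upsampling and cropping).  Its adjoint is scatter-add.
ad_gather <- function(x, idx, dims = NULL) {
  x <- as_ad(x)
  n_in <- length(x$v)
  v <- gather_num(x$v, idx)
  if (!is.null(dims)) dim(v) <- dims
  din <- dim(x$v)
  ad_node(v, list(x), req = x$req,
          vjp = function(g, node) list(ad_scatter(g, idx, n_in, dims = din)))
}

ad_scatter <- function(x, idx, n, dims = NULL) {
  x <- as_ad(x)
  v <- scatter_num(x$v, idx, n)
  if (!is.null(dims)) dim(v) <- dims
  din <- dim(x$v)
  ad_node(v, list(x), req = x$req,
          vjp = function(g, node) list(ad_gather(g, idx, dims = din)))
}

gather_num <- function(v, idx) gather_cpp(v, idx)

scatter_num <- function(v, idx, n) scatter_add_cpp(v, idx, as.integer(n))

ad_sum <- function(x) {
  x <- as_ad(x)
  n <- length(x$v); dims <- dim(x$v)
  ad_node(sum(x$v), list(x), req = x$req,
          vjp = function(g, node) list(ad_gather(g, rep(1L, n), dims = dims)))
}

ad_mean <- function(x) ad_mul(ad_sum(x), 1 / length(as_ad(x)$v))

ad_relu <- function(x) {
  x <- as_ad(x)
  mask <- as.numeric(x$v > 0); dim(mask) <- dim(x$v)
  v <- x$v * mask
  ad_node(v, list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, ad_const(mask))))
}

ad_lrelu <- function(x, slope = 0.01) {
  x <- as_ad(x)
  mask <- ifelse(x$v > 0, 1, slope); dim(mask) <- dim(x$v)
  ad_node(x$v * mask, list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, ad_const(mask))))
}

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  v <- 1 / (1 + exp(-x$v))
  ad_node(v, list(x), req = x$req,
          vjp = function(g, node)
            list(ad_mul(ad_mul(g, node), ad_sub(ad_const(1), node))))
}

ad_exp <- function(x) {
  x <- as_ad(x)
  ad_node(exp(x$v), list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, node)))
}

ad_log <- function(x) {
  x <- as_ad(x)
  ad_node(log(x$v), list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, ad_recip(node$parents[[1]]))))
}

ad_recip <- function(x) {
  x <- as_ad(x)
  ad_node(1 / x$v, list(x), req = x$req,
          vjp = function(g, node) list(ad_neg(ad_mul(g, ad_mul(node, node)))))
}

ad_sqrt <- function(x) {
  x <- as_ad(x)
  ad_node(sqrt(x$v), list(x), req = x$req,
          vjp = function(g, node)
            list(ad_mul(g, ad_recip(ad_mul(ad_const(2), node)))))
}

ad_abs <- function(x) {
  x <- as_ad(x)
  s <- sign(x$v); dim(s) <- dim(x$v)
  ad_node(abs(x$v), list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, ad_const(s))))
}

ad_clamp_min <- function(x, lo) {
  x <- as_ad(x)
  mask <- as.numeric(x$v > lo); dim(mask) <- dim(x$v)
  ad_node(pmax(x$v, lo), list(x), req = x$req,
          vjp = function(g, node) list(ad_mul(g, ad_const(mask))))
}

#' Backward pass: gradients of a node with respect to a set of leaves
#'
#' Gradients are returned as graph nodes, so they can themselves be
#' differentiated (needed for the gradient penalty).
#'
#' @param root Node to differentiate (typically scalar).
#' @param wrt List of leaf nodes.
#' @param seed Optional seed gradient node (defaults to ones).
#' @return List of `adnode` gradients aligned with `wrt` (zero nodes where
#'   `root` does not depend on a leaf).
#' @keywords internal
ad_grad <- function(root, wrt, seed = NULL) {
  if (is.null(seed)) seed <- ad_const(rep(1, length(root$v)))
  # Reachable req-subgraph.  The work stack holds integer node ids, not the
  # node lists themselves: list subassignment would trigger R's recursive
  # duplication of the whole captured graph on every push.
  nodes <- new.env(parent = emptyenv())
  nodes[[as.character(root$id)]] <- root
  stack <- integer(1024L)
  stack[1L] <- root$id
  top <- 1L
  while (top > 0L) {
    n <- nodes[[as.character(stack[top])]]; top <- top - 1L
    for (p in n$parents) {
      if (!p$req) next
      k <- as.character(p$id)
      if (is.null(nodes[[k]])) {
        nodes[[k]] <- p
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, integer(length(stack)))
        stack[top] <- p$id
      }
    }
  }
  grads <- new.env(parent = emptyenv())
  grads[[as.character(root$id)]] <- seed
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  for (id in ids) {
    key <- as.character(id)
    n <- nodes[[key]]
    g <- grads[[key]]
    if (is.null(g) || !length(n$parents)) next
    pg <- n$vjp(g, n)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!p$req || is.null(pg[[i]])) next
      pk <- as.character(p$id)
      grads[[pk]] <- if (is.null(grads[[pk]])) pg[[i]] else ad_add(grads[[pk]], pg[[i]])
    }
  }
  lapply(wrt, function(w) {
    g <- grads[[as.character(w$id)]]
    if (is.null(g)) {
      z <- numeric(length(w$v)); dim(z) <- dim(w$v)
      g <- ad_const(z)
    } else if (!identical(dim(g$v), dim(w$v)) && length(g$v) == length(w$v)) {
      dim(g$v) <- dim(w$v)
    }
    g
  })
}
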