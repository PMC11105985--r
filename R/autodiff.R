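# Minimal reverse-mode autodiff tape over dense real arrays.
#
# Feature maps use layout (H, W, B, C): column-major folding of the first three
# axes gives the (H*W*B) x C matrix that every channel-mixing op needs, so all
# heavy lifting is plain BLAS matmul. The tape records only nodes that require
# gradients; backward() walks it in reverse creation order.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$n <- 0L

ad_tape_reset <- function() {
  .ad$tape <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_record <- function(nd) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- nd
  .ad$n <- n
  nd
}

ad_node <- function(val, parents = list(), backfn = NULL) {
  needs <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$needs, logical(1L)))
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$needs <- needs
  nd$grad <- NULL
  if (needs) ad_record(nd)
  nd
}

# leaf with gradient tracking (optimization variable or trainable parameter)
ad_leaf <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- list()
  nd$backfn <- NULL
  nd$needs <- TRUE
  nd$grad <- NULL
  nd
}

ad_const <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- list()
  nd$backfn <- NULL
  nd$needs <- FALSE
  nd$grad <- NULL
  nd
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$val)

ad_accum <- function(p, g) {
  if (p$needs) p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Seed `root` with `grad` and sweep the tape backwards. Leaves keep their
# accumulated gradients; call ad_zero_grad() on them between steps.
ad_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = if (is.null(dim(root$val))) length(root$val) else dim(root$val))
  root$grad <- if (is.null(root$grad)) grad else root$grad + grad
  if (.ad$n > 0L) {
    for (i in .ad$n:1L) {
      nd <- .ad$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
    }
  }
  invisible(NULL)
}

ad_zero_grad <- function(leaves) {
  for (p in leaves) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise ops --------------------------------------------------------

ad_add <- function(a, b) {
  ad_node(a$val + b$val, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], nd$grad)
  })
}

ad_sub <- function(a, b) {
  ad_node(a$val - b$val, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], -nd$grad)
  })
}

ad_scale <- function(a, k) {
  ad_node(a$val * k, list(a), function(nd) ad_accum(nd$parents[[1L]], nd$grad * k))
}

ad_mul <- function(a, b) {
  ad_node(a$val * b$val, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$val)
    ad_accum(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$val)
  })
}

ad_lrelu <- function(a, slope = 0.2) {
  m <- slope + (1 - slope) * (a$val >= 0)
  ad_node(a$val * m, list(a), function(nd) ad_accum(nd$parents[[1L]], nd$grad * m))
}

ad_softplus <- function(a) {
  # numerically stable softplus and its sigmoid derivative
  v <- a$val
  out <- log1p(exp(pmin(v, 30)))
  hi <- v > 30
  if (any(hi)) out[hi] <- v[hi]
  ad_node(out, list(a), function(nd) {
    s <- 1 / (1 + exp(pmin(pmax(-v, -30), 30)))
    ad_accum(nd$parents[[1L]], nd$grad * s)
  })
}

ad_tanh <- function(a) {
  t <- tanh(a$val)
  ad_node(t, list(a), function(nd) ad_accum(nd$parents[[1L]], nd$grad * (1 - t^2)))
}

ad_reshape <- function(a, dims) {
  v <- a$val
  od <- dim(v)
  dim(v) <- dims
  ad_node(v, list(a), function(nd) {
    g <- nd$grad
    dim(g) <- od
    ad_accum(nd$parents[[1L]], g)
  })
}

## ---- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  ad_node(sum(a$val), list(a), function(nd) {
    g <- array(as.numeric(nd$grad), dim = dim(nd$parents[[1L]]$val))
    ad_accum(nd$parents[[1L]], g)
  })
}

# sum of squared residuals against a fixed target array
ad_sse <- function(a, target) {
  r <- a$val - target
  ad_node(sum(r * r), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], (2 * as.numeric(nd$grad)) * r)
  })
}

# sum of squares of the node itself (weight-decay style penalty)
ad_ssq <- function(a) {
  ad_node(sum(a$val^2), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], (2 * as.numeric(nd$grad)) * nd$parents[[1L]]$val)
  })
}

## ---- dense / channel ops ----------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    ad_accum(nd$parents[[1L]], g %*% t(nd$parents[[2L]]$val))
    ad_accum(nd$parents[[2L]], t(nd$parents[[1L]]$val) %*% g)
  })
}

# add per-channel bias b (length C) to features (H, W, B, C)
ad_bias <- function(x, b) {
  d <- dim(x$val)
  C <- d[length(d)]
  m <- prod(d) / C
  ad_node(x$val + rep(b$val, each = m), list(x, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], colSums(matrix(nd$grad, m, C)))
  })
}

# multiply features (H, W, B, C) by per-sample per-channel styles s (B, C)
ad_chanscale <- function(x, s) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; C <- d[4L]
  sv <- rep(as.vector(s$val), each = H * W)
  ad_node(x$val * sv, list(x, s), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * sv)
    t <- nd$grad * nd$parents[[1L]]$val
    dim(t) <- c(H * W, B * C)
    ds <- colSums(t)
    dim(ds) <- c(B, C)
    ad_accum(nd$parents[[2L]], ds)
  })
}

## ---- spatial ops ------------------------------------------------------------

ad_upsample2 <- function(x) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]
  y <- x$val[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , , drop = FALSE]
  ad_node(y, list(x), function(nd) {
    g <- nd$grad
    o <- seq(1L, 2L * H, by = 2L); e <- o + 1L
    ow <- seq(1L, 2L * W, by = 2L); ew <- ow + 1L
    dx <- g[o, ow, , , drop = FALSE] + g[o, ew, , , drop = FALSE] +
      g[e, ow, , , drop = FALSE] + g[e, ew, , , drop = FALSE]
    ad_accum(nd$parents[[1L]], dx)
  })
}

ad_avgpool2 <- function(x) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]
  o <- seq(1L, H, by = 2L); e <- o + 1L
  ow <- seq(1L, W, by = 2L); ew <- ow + 1L
  y <- 0.25 * (x$val[o, ow, , , drop = FALSE] + x$val[o, ew, , , drop = FALSE] +
                 x$val[e, ow, , , drop = FALSE] + x$val[e, ew, , , drop = FALSE])
  ad_node(y, list(x), function(nd) {
    g <- 0.25 * nd$grad
    dx <- array(0, d)
    dx[o, ow, , ] <- g
    dx[o, ew, , ] <- dx[o, ew, , , drop = FALSE] + g
    dx[e, ow, , ] <- dx[e, ow, , , drop = FALSE] + g
    dx[e, ew, , ] <- dx[e, ew, , , drop = FALSE] + g
    ad_accum(nd$parents[[1L]], dx)
  })
}

# central crop (H, W, B, C) -> (h, w, B, C); backward zero-pads
ad_crop <- function(x, h, w) {
  d <- dim(x$val)
  i0 <- (d[1L] - h) %/% 2L
  j0 <- (d[2L] - w) %/% 2L
  ri <- (i0 + 1L):(i0 + h)
  rj <- (j0 + 1L):(j0 + w)
  ad_node(x$val[ri, rj, , , drop = FALSE], list(x), function(nd) {
    dx <- array(0, d)
    dx[ri, rj, , ] <- nd$grad
    ad_accum(nd$parents[[1L]], dx)
  })
}

# 3x3 same-size convolution with zero padding (compiled kernel).
# x: (H, W, B, Cin), W: (3, 3, Cin, Cout) -> (H, W, B, Cout)
ad_conv3 <- function(x, w) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; C <- d[4L]
  Cout <- dim(w$val)[4L]
  y <- conv3_fwd_cpp(x$val, w$val, H, W, B, C, Cout)
  ad_node(y, list(x, w), function(nd) {
    g <- nd$grad
    xn <- nd$parents[[1L]]; wn <- nd$parents[[2L]]
    if (wn$needs) ad_accum(wn, conv3_bwd_w_cpp(g, xn$val, H, W, B, C, Cout))
    if (xn$needs) ad_accum(xn, conv3_bwd_x_cpp(g, wn$val, H, W, B, C, Cout))
  })
}

# 1x1 convolution: channel mixing by matrix w (Cin x Cout) plus bias (Cout)
ad_conv1 <- function(x, w, b) {
  d <- dim(x$val)
  C <- d[4L]; Cout <- ncol(w$val)
  m <- prod(d[1:3])
  xm <- x$val
  dim(xm) <- c(m, C)
  y <- xm %*% w$val + rep(b$val, each = m)
  dim(y) <- c(d[1L], d[2L], d[3L], Cout)
  ad_node(y, list(x, w, b), function(nd) {
    g <- nd$grad
    dim(g) <- c(m, Cout)
    xn <- nd$parents[[1L]]; wn <- nd$parents[[2L]]; bn <- nd$parents[[3L]]
    if (xn$needs) {
      dx <- g %*% t(wn$val)
      dim(dx) <- d
      ad_accum(xn, dx)
    }
    if (wn$needs) ad_accum(wn, crossprod(xm, g))
    if (bn$needs) ad_accum(bn, colSums(g))
  })
}

## ---- Adam -------------------------------------------------------------------

# leaves: named or unnamed list of ad_leaf nodes sharing one optimizer state
adam_init <- function(leaves, lr = 0.01, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(leaves, function(p) array(0, dim = dim(p$val) %||% length(p$val))),
    v = lapply(leaves, function(p) array(0, dim = dim(p$val) %||% length(p$val)))
  )
}

adam_step <- function(state, leaves, lr = NULL) {
  if (is.null(lr)) lr <- state$lr
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr <- sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (i in seq_along(leaves)) {
    p <- leaves[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    p$val <- p$val - lr * corr * state$m[[i]] / (sqrt(state$v[[i]]) + state$eps)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scale all leaf gradients so their global l2 norm is at most max_norm
clip_grads <- function(leaves, max_norm) {
  gn <- 0
  for (p in leaves) if (!is.null(p$grad)) gn <- gn + sum(p$grad^2)
  gn <- sqrt(gn)
  if (is.finite(gn) && gn > max_norm) {
    s <- max_norm / gn
    for (p in leaves) if (!is.null(p$grad)) p$grad <- p$grad * s
  }
  invisible(gn)
}

# add per-sample per-channel offsets s (B, C) to features (H, W, B, C)
ad_chanadd <- function(x, s) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]; B <- d[3L]; C <- d[4L]
  sv <- rep(as.vector(s$val), each = H * W)
  ad_node(x$val + sv, list(x, s), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    if (nd$parents[[2L]]$needs) {
      g <- nd$grad
      dim(g) <- c(H * W, B * C)
      ds <- colSums(g)
      dim(ds) <- c(B, C)
      ad_accum(nd$parents[[2L]], ds)
    }
  })
}
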