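#' Miniature multi-resolution style-based generator
#'
#' Defines a desk-scale style-based synthesis network: a learned constant
#' 4x4 feature map followed by per-resolution blocks (nearest-neighbour
#' upsampling, a 3x3 convolution whose input channels are scaled by a
#' per-level style vector, leaky-ReLU) with skip "toRGB" outputs summed
#' across resolutions. Each level consumes its own latent vector (the
#' "w-plus" convention), so inversion can optimize every resolution
#' independently. A two-layer mapping network turns Gaussian draws into
#' latent initializations.
#'
#' @param resolution output resolution, a power of two (default 64)
#' @param base base resolution of the learned constant (default 4)
#' @param latent_dim width of each per-level latent vector (default 64)
#' @param channels optional integer vector of per-level output channels
#'   (coarse to fine); default halves from 64 down to a floor of 8
#' @param output output squashing: `"linear"`, `"magnitude"` (softplus,
#'   nonnegative) or `"phase"` (pi * tanh, values in (-pi, pi))
#' @return a `generator_spec` object
#' @export
generator_spec <- function(resolution = 64L, base = 4L, latent_dim = 64L,
                           channels = NULL, output = c("linear", "magnitude", "phase")) {
  output <- match.arg(output)
  L <- as.integer(round(log2(resolution / base))) + 1L
  if (base * 2^(L - 1L) != resolution || L < 2L)
    stop("resolution must be base * 2^(L-1) for integer L >= 2")
  if (is.null(channels)) channels <- pmax(8L, as.integer(64 / 2^(0:(L - 1L))))
  if (length(channels) != L) stop("channels must have one entry per level")
  structure(list(resolution = as.integer(resolution), base = as.integer(base),
                 latent_dim = as.integer(latent_dim), levels = L,
                 channels = as.integer(channels), output = output),
            class = "generator_spec")
}

#' Initialize generator parameters
#'
#' @param spec a [generator_spec()]
#' @param seed RNG seed
#' @return a `generator` object (spec plus parameter list)
#' @export
generator_init <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  L <- spec$levels; ld <- spec$latent_dim; ch <- spec$channels
  cin <- c(ch[1L], ch[-L])     # input channels per level (level 1 reads the constant)
  p <- list(
    const = array(stats::rnorm(spec$base^2 * ch[1L], sd = 1), c(spec$base, spec$base, 1L, ch[1L])),
    map_W1 = matrix(stats::rnorm(ld * ld, sd = 1 / sqrt(ld)), ld, ld),
    map_b1 = numeric(ld),
    map_W2 = matrix(stats::rnorm(ld * ld, sd = 1 / sqrt(ld)), ld, ld),
    map_b2 = numeric(ld),
    A = vector("list", L), W = vector("list", L), b = vector("list", L),
    Wr = vector("list", L), br = vector("list", L)
  )
  p$nz <- vector("list", L)
  p$Bs <- vector("list", L)
  p$Rg <- vector("list", L)
  for (l in seq_len(L)) {
    p$A[[l]] <- matrix(stats::rnorm(ld * cin[l], sd = 0.25 / sqrt(ld)), ld, cin[l])
    p$Bs[[l]] <- matrix(stats::rnorm(ld * ch[l], sd = 0.25 / sqrt(ld)), ld, ch[l])
    p$Rg[[l]] <- matrix(stats::rnorm(ld, sd = 0.25 / sqrt(ld)), ld, 1L)
    p$W[[l]] <- array(stats::rnorm(9 * cin[l] * ch[l], sd = sqrt(2 / (9 * cin[l]))),
                      c(3L, 3L, cin[l], ch[l]))
    p$b[[l]] <- numeric(ch[l])
    p$Wr[[l]] <- matrix(stats::rnorm(ch[l], sd = 0.5 / sqrt(ch[l])), ch[l], 1L)
    p$br[[l]] <- numeric(1L)
    # per-pixel noise buffer, zero until subject adaptation tunes it (frozen
    # again afterwards): absorbs subject-specific fine detail
    res_l <- spec$base * 2^(l - 1L)
    p$nz[[l]] <- matrix(0, res_l, res_l)
  }
  structure(list(spec = spec, params = p), class = "generator")
}

# wrap a parameter list into tape nodes; trainable parameters become leaves
gen_wrap <- function(params, trainable = FALSE) {
  wrap1 <- function(v) if (trainable) ad_leaf(v) else ad_const(v)
  out <- params
  for (nm in c("const", "map_W1", "map_b1", "map_W2", "map_b2"))
    out[[nm]] <- wrap1(params[[nm]])
  for (nm in c("A", "W", "b", "Wr", "br", "nz", "Bs", "Rg"))
    out[[nm]] <- lapply(params[[nm]], wrap1)
  out
}

# flat list of the synthesis leaves (order fixed; mapping net excluded)
gen_leaves <- function(pw) {
  c(list(pw$const), pw$A, pw$W, pw$b, pw$Wr, pw$br, pw$nz, pw$Bs, pw$Rg)
}

# write values (in gen_leaves order) back into a plain parameter list
gen_set_leaves <- function(params, values) {
  L <- length(params$A)
  k <- 1L
  params$const <- values[[k]]
  for (nm in c("A", "W", "b", "Wr", "br", "nz", "Bs", "Rg")) {
    for (l in seq_len(L)) {
      k <- k + 1L
      v <- values[[k]]
      if (nm %in% c("b", "br")) v <- as.vector(v)
      params[[nm]][[l]] <- v
    }
  }
  params
}

# latents: list of L matrices (B x latent_dim), possibly tape nodes
as_latent_nodes <- function(latents, trainable = FALSE) {
  lapply(latents, function(w) {
    if (ad_is_node(w)) w else if (trainable) ad_leaf(w) else ad_const(w)
  })
}

latent_batch <- function(latents) nrow(if (ad_is_node(latents[[1L]])) latents[[1L]]$val else latents[[1L]])

check_latents <- function(spec, latents) {
  if (length(latents) != spec$levels) stop("latent stack must have one level per synthesis level")
  for (w in latents) {
    v <- if (ad_is_node(w)) w$val else w
    if (!is.matrix(v) || ncol(v) != spec$latent_dim || !all(is.finite(v)))
      stop("each latent level must be a finite B x latent_dim matrix")
  }
  invisible(TRUE)
}

# broadcast-add a (H, W) noise buffer onto (H, W, B, C) features
ad_noise <- function(x, nz) {
  d <- dim(x$val)
  ad_node(x$val + as.vector(nz$val), list(x, nz), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    if (nd$parents[[2L]]$needs) {
      g <- nd$grad
      dim(g) <- c(d[1L] * d[2L], d[3L] * d[4L])
      ad_accum(nd$parents[[2L]], matrix(rowSums(g), d[1L], d[2L]))
    }
  })
}

# one synthesis level: modulate -> conv3 -> bias -> noise -> lrelu; skip update
gen_level <- function(pw, spec, l, x, y, wl) {
  if (l > 1L) {
    x <- ad_upsample2(x)
    if (!is.null(y)) y <- ad_upsample2(y)
  }
  ones <- matrix(1, nrow(wl$val), ncol(pw$A[[l]]$val))
  s <- ad_add(ad_const(ones), ad_matmul(wl, pw$A[[l]]))
  x <- ad_conv3(ad_chanscale(x, s), pw$W[[l]])
  x <- ad_chanadd(ad_bias(x, pw$b[[l]]), ad_matmul(wl, pw$Bs[[l]]))
  x <- ad_lrelu(ad_noise(x, pw$nz[[l]]))
  rgb <- ad_conv1(x, pw$Wr[[l]], pw$br[[l]])
  g1 <- matrix(1, nrow(wl$val), 1L)
  rgb <- ad_chanscale(rgb, ad_add(ad_const(g1), ad_matmul(wl, pw$Rg[[l]])))
  y <- if (is.null(y)) rgb else ad_add(y, rgb)
  list(x = x, y = y)
}

gen_out_act <- function(y, output) {
  switch(output, linear = y, magnitude = ad_softplus(y), phase = ad_scale(ad_tanh(y), pi))
}

# full forward on the tape; latents must already be nodes. Returns output node.
gen_forward <- function(pw, spec, latents, from = 1L, x = NULL, y = NULL) {
  if (from == 1L) {
    B <- latent_batch(latents)
    xv <- pw$const$val[, , rep(1L, B), , drop = FALSE]
    # tile constant over batch; gradient sums over batch copies
    x <- ad_node(xv, list(pw$const), function(nd) {
      g <- nd$grad
      gs <- array(0, dim(pw$const$val))
      for (bb in seq_len(dim(g)[3L])) gs <- gs + g[, , bb, , drop = FALSE]
      ad_accum(nd$parents[[1L]], gs)
    })
    y <- NULL
  }
  for (l in from:spec$levels) {
    st <- gen_level(pw, spec, l, x, y, latents[[l]])
    x <- st$x; y <- st$y
  }
  gen_out_act(y, spec$output)
}

#' Synthesize images from a latent stack
#'
#' Deterministic forward pass of the generator. Latents are a list with one
#' `B x latent_dim` matrix per synthesis level.
#'
#' @param gen a `generator` object
#' @param latents latent stack (see [random_latents()])
#' @return an `resolution x resolution` matrix for a single image, or an
#'   `H x W x B` array for a batch
#' @export
synthesize <- function(gen, latents) {
  check_latents(gen$spec, latents)
  ad_tape_reset()
  pw <- gen_wrap(gen$params, trainable = FALSE)
  out <- gen_forward(pw, gen$spec, as_latent_nodes(latents))
  v <- out$val
  d <- dim(v)
  if (d[3L] == 1L) matrix(v, d[1L], d[2L]) else array(v, d[1:3])
}

#' Partition the generator for intermediate-layer optimization
#'
#' Splits the synthesis network into a head (levels `1..split-1`) and a tail
#' (levels `split..L`). The head's output — the hidden feature map plus the
#' accumulated skip image — is the intermediate activation that inversion
#' optimizes directly before projecting it back onto the head's range.
#'
#' @param gen a `generator` object
#' @param split split level, `2 <= split <= L`
#' @return a list with `head` and `tail` closures and bookkeeping
#' @export
generator_partition <- function(gen, split) {
  L <- gen$spec$levels
  split <- as.integer(split)
  if (split < 2L || split > L) stop("split must satisfy 2 <= split <= number of levels")
  list(split = split,
       head = function(latents) head_forward(gen, latents, split),
       tail = function(wint, latents) tail_forward(gen, wint, latents, split))
}

#' @rdname generator_partition
#' @param latents latent stack; only levels below `split` are consumed
#' @export
head_forward <- function(gen, latents, split) {
  check_latents(gen$spec, latents)
  ad_tape_reset()
  pw <- gen_wrap(gen$params, trainable = FALSE)
  ln <- as_latent_nodes(latents)
  B <- latent_batch(ln)
  xv <- gen$params$const[, , rep(1L, B), , drop = FALSE]
  x <- ad_const(xv); y <- NULL
  for (l in seq_len(split - 1L)) {
    st <- gen_level(pw, gen$spec, l, x, y, ln[[l]])
    x <- st$x; y <- st$y
  }
  list(x = x$val, y = y$val)
}

#' @rdname generator_partition
#' @param wint intermediate activation, a list with feature map `x` and skip
#'   image `y` as produced by [head_forward()]
#' @export
tail_forward <- function(gen, wint, latents, split) {
  check_latents(gen$spec, latents)
  ad_tape_reset()
  pw <- gen_wrap(gen$params, trainable = FALSE)
  ln <- as_latent_nodes(latents)
  out <- gen_forward(pw, gen$spec, ln, from = split,
                     x = ad_const(wint$x), y = ad_const(wint$y))
  v <- out$val
  d <- dim(v)
  if (d[3L] == 1L) matrix(v, d[1L], d[2L]) else array(v, d[1:3])
}

## ---- mapping network and latent draws --------------------------------------

map_forward_raw <- function(p, z) {
  h <- z %*% p$map_W1 + rep(p$map_b1, each = nrow(z))
  h <- ifelse(h >= 0, h, 0.2 * h)
  w <- h %*% p$map_W2 + rep(p$map_b2, each = nrow(z))
  ifelse(w >= 0, w, 0.2 * w)
}

#' Draw latent stacks via the mapping network
#'
#' Gaussian draws are passed through the mapping network and replicated to
#' every synthesis level (each level then evolves independently under
#' optimization).
#'
#' @param gen a `generator` object
#' @param n number of images
#' @param seed RNG seed
#' @return a latent stack (list of `n x latent_dim` matrices)
#' @export
random_latents <- function(gen, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ld <- gen$spec$latent_dim
  z <- matrix(stats::rnorm(n * ld), n, ld)
  w <- map_forward_raw(gen$params, z)
  rep(list(w), gen$spec$levels)
}

#' Mean latent of the mapping network
#'
#' Average mapped latent over Gaussian draws; the standard initialization for
#' network inversion.
#'
#' @param gen a `generator` object
#' @param n_draws number of Gaussian draws (default 10000)
#' @param seed RNG seed
#' @return a latent stack with identical `1 x latent_dim` rows per level
#' @export
mean_latent <- function(gen, n_draws = 10000L, seed = 1L) {
  set.seed(seed)
  ld <- gen$spec$latent_dim
  z <- matrix(stats::rnorm(n_draws * ld), n_draws, ld)
  w <- colMeans(map_forward_raw(gen$params, z))
  rep(list(matrix(w, 1L, ld)), gen$spec$levels)
}

## ---- discriminator and adversarial pretraining ------------------------------

disc_init <- function(resolution, seed = 0L) {
  set.seed(seed + 7L)
  nlev <- as.integer(round(log2(resolution / 4L)))
  ch <- pmin(64L, 8L * 2^(0:nlev))
  p <- list(from_W = matrix(stats::rnorm(ch[1L], sd = 1), 1L, ch[1L]), from_b = numeric(ch[1L]),
            W = vector("list", nlev), b = vector("list", nlev))
  for (l in seq_len(nlev)) {
    p$W[[l]] <- array(stats::rnorm(9 * ch[l] * ch[l + 1L], sd = sqrt(2 / (9 * ch[l]))),
                      c(3L, 3L, ch[l], ch[l + 1L]))
    p$b[[l]] <- numeric(ch[l + 1L])
  }
  cfin <- ch[nlev + 1L] * 16L
  p$fc_W <- matrix(stats::rnorm(cfin * 32L, sd = 1 / sqrt(cfin)), cfin, 32L)
  p$fc_b <- numeric(32L)
  p$out_W <- matrix(stats::rnorm(32L, sd = 1 / sqrt(32)), 32L, 1L)
  p$out_b <- numeric(1L)
  p
}

disc_wrap <- function(p, trainable) {
  wrap1 <- function(v) if (trainable) ad_leaf(v) else ad_const(v)
  out <- p
  for (nm in c("from_W", "from_b", "fc_W", "fc_b", "out_W", "out_b")) out[[nm]] <- wrap1(p[[nm]])
  out$W <- lapply(p$W, wrap1); out$b <- lapply(p$b, wrap1)
  out
}

disc_leaves <- function(dw) c(list(dw$from_W, dw$from_b, dw$fc_W, dw$fc_b, dw$out_W, dw$out_b), dw$W, dw$b)

disc_forward <- function(dw, x) {
  h <- ad_lrelu(ad_conv1(x, dw$from_W, dw$from_b))
  for (l in seq_along(dw$W)) {
    h <- ad_avgpool2(ad_lrelu(ad_bias(ad_conv3(h, dw$W[[l]]), dw$b[[l]])))
  }
  d <- dim(h$val)
  B <- d[3L]
  # flatten (4,4,B,C) -> (B, 16C)
  hm <- ad_node(
    { t <- aperm(h$val, c(1L, 2L, 4L, 3L)); dim(t) <- c(d[1L] * d[2L] * d[4L], B); t(t) },
    list(h), function(nd) {
      g <- t(nd$grad)
      dim(g) <- c(d[1L], d[2L], d[4L], B)
      ad_accum(nd$parents[[1L]], aperm(g, c(1L, 2L, 4L, 3L)))
    })
  h2 <- ad_lrelu(ad_bias2(ad_matmul(hm, dw$fc_W), dw$fc_b))
  ad_bias2(ad_matmul(h2, dw$out_W), dw$out_b)
}

# bias over columns of a (B x C) matrix
ad_bias2 <- function(x, b) {
  B <- nrow(x$val)
  ad_node(x$val + rep(b$val, each = B), list(x, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], colSums(nd$grad))
  })
}

# mean softplus(sign * logits) of a (B x 1) score node
gan_loss <- function(logits, sign) {
  B <- nrow(logits$val)
  ad_scale(ad_sum(ad_softplus(ad_scale(logits, sign))), 1 / B)
}

#' Adversarially pretrain the generator on a phantom corpus
#'
#' Non-saturating logistic GAN training of the miniature generator against a
#' small convolutional critic, stabilized at desk scale with instance noise
#' and critic weight decay. Determinism follows from the seed.
#'
#' @param spec a [generator_spec()] (output should be `"magnitude"` or
#'   `"phase"` to match the corpus)
#' @param corpus array `resolution x resolution x n_images` of training images
#' @param steps number of optimization steps (generator updates)
#' @param batch batch size (default 16 at desk scale)
#' @param lr Adam step size
#' @param seed RNG seed
#' @param noise_sd instance-noise standard deviation for the critic inputs
#' @param verbose print progress every 50 steps
#' @return a `generator` object with a `history` element (per-step G/D losses)
#' @export
pretrain_generator <- function(spec, corpus, steps = 300L, batch = 16L,
                               lr = 1e-3, seed = 0L, noise_sd = 0.1,
                               verbose = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  nimg <- dim(corpus)[3L]
  if (nimg < 200L) warning("pretraining corpus has fewer than 200 images; proceeding")
  if (dim(corpus)[1L] != spec$resolution || dim(corpus)[2L] != spec$resolution)
    stop("corpus images must match the generator resolution")
  set.seed(seed)
  gen <- generator_init(spec, seed = seed)
  dp <- disc_init(spec$resolution, seed = seed)
  pw <- gen_wrap(gen$params, trainable = TRUE)
  g_leaves <- c(gen_leaves(pw), list(pw$map_W1, pw$map_b1, pw$map_W2, pw$map_b2))
  dwn <- disc_wrap(dp, trainable = TRUE)
  d_leaves <- disc_leaves(dwn)
  g_opt <- adam_init(g_leaves, lr = lr)
  d_opt <- adam_init(d_leaves, lr = lr / 3)
  hist <- matrix(NA_real_, steps, 2L, dimnames = list(NULL, c("g_loss", "d_loss")))
  ld <- spec$latent_dim
  for (it in seq_len(steps)) {
    # --- generator step (critic frozen)
    z <- matrix(stats::rnorm(batch * ld), batch, ld)
    ad_tape_reset()
    wnode <- map_forward_ad(pw, z)
    fake <- gen_forward(pw, spec, rep(list(wnode), spec$levels))
    dfro <- disc_wrap(list2params(dwn), trainable = FALSE)
    lg <- gan_loss(disc_forward(dfro, fake), -1)
    # moment-matching stabilizer: keep the fake batch's first two moments
    # near the real data's, preventing collapse through the saturating
    # output nonlinearity at desk scale
    ridx <- sample.int(nimg, batch, replace = nimg < batch)
    rb <- corpus[, , ridx]
    n_el <- length(fake$val)
    m1 <- ad_scale(ad_sum(fake), 1 / n_el)
    m2 <- ad_scale(ad_sum(ad_mul(fake, fake)), 1 / n_el)
    mom <- ad_add(ad_sse(m1, mean(rb)), ad_sse(m2, mean(rb^2)))
    lg <- ad_add(lg, ad_scale(mom, 10))
    ad_zero_grad(g_leaves)
    ad_backward(lg)
    clip_grads(g_leaves, 5)
    g_opt <- adam_step(g_opt, g_leaves)
    fake_v <- fake$val
    # --- critic step (generator output detached)
    idx <- sample.int(nimg, batch, replace = nimg < batch)
    real <- array(corpus[, , idx], c(spec$resolution, spec$resolution, batch, 1L))
    real <- real + stats::rnorm(length(real), sd = noise_sd)
    fake_n <- fake_v + stats::rnorm(length(fake_v), sd = noise_sd)
    ad_tape_reset()
    ldl <- ad_add(gan_loss(disc_forward(dwn, ad_const(real)), -1),
                  gan_loss(disc_forward(dwn, ad_const(fake_n)), +1))
    # keep the critic from running away at desk scale: update it only while
    # it still makes mistakes (its loss stays above a margin)
    if (ldl$val > 0.4) {
      ad_zero_grad(d_leaves)
      ad_backward(ldl)
      for (p in d_leaves) if (!is.null(p$grad)) p$grad <- p$grad + 1e-4 * p$val
      clip_grads(d_leaves, 5)
      d_opt <- adam_step(d_opt, d_leaves)
    }
    hist[it, ] <- c(lg$val, ldl$val)
    if (verbose && it %% 50L == 0L)
      message(sprintf("pretrain step %d: G %.3f D %.3f", it, lg$val, ldl$val))
  }
  gen$params <- list2params(pw)
  gen$history <- hist
  gen
}

# mapping network on the tape (batch z fixed)
map_forward_ad <- function(pw, z) {
  h <- ad_lrelu(ad_bias2(ad_matmul(ad_const(z), pw$map_W1), pw$map_b1))
  ad_lrelu(ad_bias2(ad_matmul(h, pw$map_W2), pw$map_b2))
}

# pull current values out of a wrapped (node) parameter list
list2params <- function(pw) {
  out <- pw
  for (nm in names(pw)) {
    if (ad_is_node(pw[[nm]])) out[[nm]] <- pw[[nm]]$val
    else if (is.list(pw[[nm]])) out[[nm]] <- lapply(pw[[nm]], function(q) if (ad_is_node(q)) q$val else q)
  }
  out
}
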