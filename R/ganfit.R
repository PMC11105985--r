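#' Euclidean projection onto an l1 ball
#'
#' Exact projection of `w` onto `{v : ||v - center||_1 <= radius}` via the
#' sorted soft-threshold construction: the threshold tau solves
#' `sum(max(|w - center| - tau, 0)) = radius`.
#'
#' @param w numeric vector
#' @param center ball center (same length)
#' @param radius nonnegative radius; 0 returns the center, Inf returns `w`
#' @return the projected vector
#' @export
project_l1_ball <- function(w, center, radius) {
  if (radius < 0) stop("radius must be >= 0")
  if (is.infinite(radius)) return(w)
  d <- w - center
  if (radius == 0) return(center)
  a <- abs(d)
  if (sum(a) <= radius) return(w)
  u <- sort(a, decreasing = TRUE)
  cs <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u > (cs - radius) / j])
  tau <- (cs[rho] - radius) / rho
  center + sign(d) * pmax(a - tau, 0)
}

lat_flatten <- function(latents) unlist(lapply(latents, as.vector), use.names = FALSE)

lat_unflatten <- function(v, template) {
  out <- template
  off <- 0L
  for (l in seq_along(template)) {
    n <- length(template[[l]])
    out[[l]] <- matrix(v[off + seq_len(n)], nrow(template[[l]]), ncol(template[[l]]))
    off <- off + n
  }
  out
}

#' Inversion configuration
#'
#' Controls the staged intermediate-layer inversion: the starting split
#' level, per-stage step budgets, Adam step size (cosine-decayed within each
#' stage), optional l1-ball chaining radii, and levels whose latents are
#' frozen.
#'
#' @param start_split first partition level (default: one below the finest)
#' @param steps_tail steps for the intermediate+tail stage, per split
#' @param steps_proj steps for projecting the intermediate activation back
#'   onto the head's range
#' @param steps_joint steps for the final joint refinement of the full stack
#' @param lr Adam step size
#' @param radius l1-ball radius (scalar, per-frame vector, or `NULL` for the
#'   default `0.1 * ||w_1||_1` chaining radius)
#' @param frozen_levels integer levels whose latents stay fixed
#' @param seed seed for any stochastic pieces
#' @return an `inversion_config` object
#' @export
inversion_config <- function(start_split = NULL, steps_tail = 300L,
                             steps_proj = 300L, steps_joint = 300L,
                             lr = 0.05, radius = NULL,
                             frozen_levels = integer(0), seed = 0L) {
  if (!is.null(radius) && any(radius < 0)) stop("radii must be >= 0")
  structure(list(start_split = start_split, steps_tail = as.integer(steps_tail),
                 steps_proj = as.integer(steps_proj), steps_joint = as.integer(steps_joint),
                 lr = lr, radius = radius, frozen_levels = as.integer(frozen_levels),
                 seed = as.integer(seed)),
            class = "inversion_config")
}

cosine_lrs <- function(lr, steps) {
  if (steps <= 0L) return(numeric(0))
  lr * 0.5 * (1 + cos(pi * (seq_len(steps) - 1L) / max(1L, steps)))
}

sse_loss_fn <- function(target) {
  force(target)
  function(img) {
    r <- img - target
    list(loss = sum(r * r), grad = 2 * r)
  }
}

# project varying levels so the FULL concatenated stack stays in the ball
ball_project_leaves <- function(leaves, vary, latents, center, radius) {
  if (is.null(center) || is.null(radius) || is.infinite(radius)) return(invisible(NULL))
  cur <- latents
  for (i in seq_along(vary)) cur[[vary[i]]] <- leaves[[i]]$val
  fixed <- setdiff(seq_along(latents), vary)
  cflat <- lat_flatten(center)
  slack <- radius
  for (l in fixed) slack <- slack - sum(abs(cur[[l]] - center[[l]]))
  vflat <- unlist(lapply(vary, function(l) as.vector(cur[[l]])))
  cpart <- unlist(lapply(vary, function(l) as.vector(center[[l]])))
  proj <- project_l1_ball(vflat, cpart, max(0, slack))
  off <- 0L
  for (i in seq_along(vary)) {
    n <- length(cur[[vary[i]]])
    leaves[[i]]$val <- matrix(proj[off + seq_len(n)],
                              nrow(cur[[vary[i]]]), ncol(cur[[vary[i]]]))
    off <- off + n
  }
  invisible(NULL)
}

# optimize latent levels `vary` (others fixed) against loss_fn on the output
optimize_latents <- function(gen, latents, vary, steps, lr, loss_fn,
                             crop = NULL, ball_center = NULL, ball_radius = NULL) {
  if (steps <= 0L || length(vary) == 0L) {
    out_img <- synth_crop(gen, latents, crop)
    return(list(latents = latents, loss = loss_fn(out_img)$loss))
  }
  spec <- gen$spec
  leaves <- lapply(vary, function(l) ad_leaf(latents[[l]]))
  opt <- adam_init(leaves, lr = lr)
  lrs <- cosine_lrs(lr, steps)
  best <- NULL; best_loss <- Inf
  pw <- gen_wrap(gen$params, trainable = FALSE)
  for (it in seq_len(steps)) {
    nodes <- latents
    for (i in seq_along(vary)) nodes[[vary[i]]] <- leaves[[i]]
    nodes <- as_latent_nodes(nodes)
    ad_tape_reset()
    img <- gen_forward(pw, spec, nodes)
    if (!is.null(crop)) img <- ad_crop(img, crop[1L], crop[2L])
    res <- loss_fn(drop3(img$val))
    if (res$loss < best_loss) {
      best_loss <- res$loss
      best <- lapply(leaves, function(p) p$val)
    }
    ad_zero_grad(leaves)
    ad_backward(img, array(res$grad, dim(img$val)))
    opt <- adam_step(opt, leaves, lr = lrs[it])
    ball_project_leaves(leaves, vary, latents, ball_center, ball_radius)
  }
  # final candidate (post-projection) may beat the running best
  nodes <- latents
  for (i in seq_along(vary)) nodes[[vary[i]]] <- leaves[[i]]$val
  fin_loss <- loss_fn(synth_crop(gen, nodes, crop))$loss
  if (fin_loss <= best_loss || !is.null(ball_center)) {
    # under a ball constraint keep the feasible (projected) iterate
    best <- lapply(leaves, function(p) p$val)
    best_loss <- min(best_loss, fin_loss)
  }
  out <- latents
  for (i in seq_along(vary)) out[[vary[i]]] <- best[[i]]
  list(latents = out, loss = best_loss)
}

drop3 <- function(v) {
  d <- dim(v)
  if (length(d) == 4L && d[3L] == 1L && d[4L] == 1L) matrix(v, d[1L], d[2L]) else v
}

synth_crop <- function(gen, latents, crop = NULL) {
  img <- synthesize(gen, latents)
  if (!is.null(crop)) img <- central_crop(img, crop[1L], crop[2L])
  img
}

central_crop <- function(m, h, w) {
  i0 <- (nrow(m) - h) %/% 2L
  j0 <- (ncol(m) - w) %/% 2L
  m[(i0 + 1L):(i0 + h), (j0 + 1L):(j0 + w), drop = FALSE]
}

central_pad <- function(m, H, W) {
  out <- matrix(0, H, W)
  i0 <- (H - nrow(m)) %/% 2L
  j0 <- (W - ncol(m)) %/% 2L
  out[(i0 + 1L):(i0 + nrow(m)), (j0 + 1L):(j0 + ncol(m))] <- m
  out
}

# stage A: optimize the intermediate activation (x, y) at `split` plus the
# tail latents; returns fitted wint and tail latents
optimize_wint <- function(gen, latents, split, steps, lr, loss_fn, crop = NULL,
                          frozen = integer(0)) {
  spec <- gen$spec
  wint0 <- head_forward(gen, latents, split)
  xleaf <- ad_leaf(wint0$x); yleaf <- ad_leaf(wint0$y)
  vary <- setdiff(seq.int(split, spec$levels), frozen)
  lat_leaves <- lapply(vary, function(l) ad_leaf(latents[[l]]))
  leaves <- c(list(xleaf, yleaf), lat_leaves)
  opt <- adam_init(leaves, lr = lr)
  lrs <- cosine_lrs(lr, steps)
  pw <- gen_wrap(gen$params, trainable = FALSE)
  for (it in seq_len(steps)) {
    nodes <- as_latent_nodes(latents)
    for (i in seq_along(vary)) nodes[[vary[i]]] <- lat_leaves[[i]]
    ad_tape_reset()
    xn <- ad_reshape(xleaf, dim(xleaf$val))
    yn <- ad_reshape(yleaf, dim(yleaf$val))
    img <- gen_forward(pw, spec, nodes, from = split, x = xn, y = yn)
    if (!is.null(crop)) img <- ad_crop(img, crop[1L], crop[2L])
    res <- loss_fn(drop3(img$val))
    ad_zero_grad(leaves)
    ad_backward(img, array(res$grad, dim(img$val)))
    opt <- adam_step(opt, leaves, lr = lrs[it])
  }
  out <- latents
  for (i in seq_along(vary)) out[[vary[i]]] <- lat_leaves[[i]]$val
  list(wint = list(x = xleaf$val, y = yleaf$val), latents = out)
}

# stage B: fit head latents to a target intermediate activation
project_head <- function(gen, latents, split, wint, steps, lr, frozen = integer(0)) {
  spec <- gen$spec
  vary <- setdiff(seq_len(split - 1L), frozen)
  leaves <- lapply(vary, function(l) ad_leaf(latents[[l]]))
  opt <- adam_init(leaves, lr = lr)
  lrs <- cosine_lrs(lr, steps)
  pw <- gen_wrap(gen$params, trainable = FALSE)
  B <- nrow(latents[[1L]])
  for (it in seq_len(steps)) {
    nodes <- as_latent_nodes(latents)
    for (i in seq_along(vary)) nodes[[vary[i]]] <- leaves[[i]]
    ad_tape_reset()
    xv <- gen$params$const[, , rep(1L, B), , drop = FALSE]
    x <- ad_const(xv); y <- NULL
    for (l in seq_len(split - 1L)) {
      st <- gen_level(pw, spec, l, x, y, nodes[[l]])
      x <- st$x; y <- st$y
    }
    loss <- ad_add(ad_sse(x, wint$x), ad_sse(y, wint$y))
    ad_zero_grad(leaves)
    ad_backward(loss)
    opt <- adam_step(opt, leaves, lr = lrs[it])
  }
  out <- latents
  for (i in seq_along(vary)) out[[vary[i]]] <- leaves[[i]]$val
  out
}

#' Intermediate-layer optimization (ILO) network inversion
#'
#' Staged inversion of the generator against a target image (or a custom
#' data-consistency loss): for each split, walking from `start_split` back
#' toward earlier layers, (A) the intermediate activation and the tail
#' latents are optimized through the tail network, then (B) the head latents
#' are fitted so the head reproduces the optimized activation; finally (C)
#' the composed full latent stack is refined jointly, respecting frozen
#' levels and any l1-ball constraint.
#'
#' @param gen a `generator` object
#' @param target real target image (generator resolution, or smaller — the
#'   loss is then taken on the central crop)
#' @param cfg an [inversion_config()]
#' @param init optional initial latent stack (default: mapping-network mean)
#' @param loss_fn optional custom loss `function(img) -> list(loss, grad)`
#'   overriding the image l2 loss (used for k-space data consistency)
#' @param ball_center optional latent stack; with `cfg$radius` constrains the
#'   full stack to an l1 ball during the joint stage
#' @return list with `latents`, final `loss`, and per-stage `stage_loss`
#' @export
ilo_invert <- function(gen, target = NULL, cfg = inversion_config(),
                       init = NULL, loss_fn = NULL, ball_center = NULL,
                       crop = NULL) {
  spec <- gen$spec
  L <- spec$levels
  if (any(cfg$frozen_levels < 1L | cfg$frozen_levels > L))
    stop("frozen levels must lie within 1..L")
  if (is.null(loss_fn)) {
    if (!all(is.finite(target))) stop("target must be finite")
    if (nrow(target) > spec$resolution) stop("target exceeds generator resolution")
    if (nrow(target) < spec$resolution) crop <- dim(target)
    loss_fn <- sse_loss_fn(target)
  }
  lat <- if (is.null(init)) mean_latent(gen, seed = cfg$seed) else init
  start <- cfg$start_split %||% max(2L, L - 1L)
  if (start < 2L || start > L) stop("start_split must be in 2..L")
  radius <- if (is.null(ball_center)) NULL
  else (cfg$radius %||% (0.1 * sum(abs(lat_flatten(ball_center)))))
  cur_loss <- loss_fn(synth_crop(gen, lat, crop))$loss
  best <- lat
  best_loss <- cur_loss
  stage_loss <- c(initial = cur_loss)
  free <- function(lv) setdiff(lv, cfg$frozen_levels)
  for (s in seq.int(start, 2L)) {
    if (cfg$steps_tail > 0L) {
      st <- optimize_wint(gen, best, s, cfg$steps_tail, cfg$lr, loss_fn, crop,
                          frozen = cfg$frozen_levels)
      lat2 <- project_head(gen, st$latents, s, st$wint, cfg$steps_proj, cfg$lr,
                           frozen = cfg$frozen_levels)
      # each stage warm-starts from the best stack found so far
      for (cand in list(st$latents, lat2)) {
        l <- loss_fn(synth_crop(gen, cand, crop))$loss
        if (l < best_loss) {
          best_loss <- l
          best <- cand
        }
      }
      stage_loss <- c(stage_loss, best_loss)
    }
  }
  jt <- optimize_latents(gen, best, free(seq_len(L)), cfg$steps_joint, cfg$lr, loss_fn,
                         crop, ball_center = ball_center, ball_radius = radius)
  if (jt$loss <= best_loss || !is.null(ball_center)) {
    # a ball constraint must return the feasible iterate even if the
    # unconstrained warm start scored lower
    best <- jt$latents
    best_loss <- jt$loss
  }
  stage_loss <- c(stage_loss, joint = best_loss)
  list(latents = best, loss = best_loss, stage_loss = stage_loss)
}

#' Invert the generator against a reference image
#'
#' Multi-stage ILO minimization of the representation error
#' `||G(w) - x||_F^2` for a magnitude-normalized reference; the first step of
#' subject-specific adaptation.
#'
#' @param gen a pretrained `generator`
#' @param xp reference image in `[0, 1]` at (or below) generator resolution
#' @param cfg an [inversion_config()]
#' @return list with `latents`, `loss`, `rel_err_pct` and `stage_loss`
#' @export
invert_reference <- function(gen, xp, cfg = inversion_config()) {
  if (!all(is.finite(xp))) stop("reference image must be finite")
  res <- ilo_invert(gen, target = xp, cfg = cfg)
  fit <- synth_crop(gen, res$latents, if (nrow(xp) < gen$spec$resolution) dim(xp) else NULL)
  res$rel_err_pct <- 100 * sqrt(sum((fit - xp)^2) / sum(xp^2))
  res
}

#' Subject-specific parameter adaptation
#'
#' With reference latents fixed, fine-tunes the synthesis parameters by
#' minimizing `||G_theta(w_p) - x_p||^2 + alpha * ||theta - theta_p||^2`.
#' One latent/parameter alternation suffices in practice; the deviation
#' penalty keeps the adapted network close to the pretrained one.
#'
#' @param gen pretrained `generator`
#' @param wp reference latents from [invert_reference()]
#' @param xp reference image
#' @param alpha deviation penalty weight (>= 0)
#' @param steps Adam steps (default 4000)
#' @param lr Adam step size
#' @return an `adaptation_result`: adapted `gen`, `latents`, `alpha`,
#'   `before_err_pct`, `after_err_pct`
#' @export
adapt_parameters <- function(gen, wp, xp, alpha = 0.001, steps = 4000L, lr = 5e-3) {
  if (alpha < 0) stop("alpha must be >= 0")
  spec <- gen$spec
  crop <- if (nrow(xp) < spec$resolution) dim(xp) else NULL
  relerr <- function(g) {
    fit <- synth_crop(g, wp, crop)
    100 * sqrt(sum((fit - xp)^2) / sum(xp^2))
  }
  before <- relerr(gen)
  pw <- gen_wrap(gen$params, trainable = TRUE)
  leaves <- gen_leaves(pw)
  p0 <- lapply(leaves, function(p) p$val)
  opt <- adam_init(leaves, lr = lr)
  lrs <- cosine_lrs(lr, steps)
  nodes <- as_latent_nodes(wp)
  best <- lapply(leaves, function(p) p$val)
  best_loss <- Inf
  xdim <- dim(xp)
  for (it in seq_len(steps)) {
    ad_tape_reset()
    img <- gen_forward(pw, spec, nodes)
    if (!is.null(crop)) img <- ad_crop(img, crop[1L], crop[2L])
    r <- drop3(img$val) - xp
    pen <- 0
    for (i in seq_along(leaves)) pen <- pen + sum((leaves[[i]]$val - p0[[i]])^2)
    loss <- sum(r * r) + alpha * pen
    if (loss < best_loss) {
      best_loss <- loss
      best <- lapply(leaves, function(p) p$val)
    }
    ad_zero_grad(leaves)
    ad_backward(img, array(2 * r, dim(img$val)))
    for (i in seq_along(leaves)) {
      g <- leaves[[i]]$grad %||% array(0, dim(p0[[i]]) %||% length(p0[[i]]))
      leaves[[i]]$grad <- g + 2 * alpha * (leaves[[i]]$val - p0[[i]])
    }
    clip_grads(leaves, 10)
    opt <- adam_step(opt, leaves, lr = lrs[it])
  }
  adapted <- gen
  adapted$params <- gen_set_leaves(gen$params, best)
  after <- relerr(adapted)
  if (after > before) {          # descent guarantee: never worse than warm start
    adapted <- gen
    after <- before
  }
  structure(list(gen = adapted, latents = wp, alpha = alpha,
                 before_err_pct = before, after_err_pct = after),
            class = "adaptation_result")
}

#' Invert a sequence of frames with chained l1-ball latent constraints
#'
#' Frame 1 is inverted from its initialization (staged ILO); each subsequent
#' frame starts from and is constrained to an l1 ball centered at the
#' previous frame's solution, encoding latent similarity across adjacent
#' contrasts.
#'
#' @param gen a `generator`
#' @param targets real array `(nx, ny, Nt)` of target frames, or a list of
#'   per-frame loss functions
#' @param cfg an [inversion_config()]; `cfg$radius` may be a scalar or a
#'   vector of length `Nt - 1`
#' @param init optional list of per-frame initial latent stacks (warm start)
#' @param loss_fns optional list of per-frame custom losses
#' @return list with `latents` (per frame), `loss` (per frame)
#' @export
invert_series <- function(gen, targets = NULL, cfg = inversion_config(),
                          init = NULL, loss_fns = NULL, crop = NULL) {
  Nt <- if (!is.null(loss_fns)) length(loss_fns) else dim(targets)[3L]
  radii <- cfg$radius
  if (!is.null(radii) && !(length(radii) %in% c(1L, Nt - 1L)))
    stop("radius must have length 1 or Nt - 1")
  if (!is.null(radii) && length(radii) == 1L) radii <- rep(radii, Nt - 1L)
  out_lat <- vector("list", Nt)
  out_loss <- numeric(Nt)
  prev <- NULL
  warm <- !is.null(init)
  for (t in seq_len(Nt)) {
    lf <- if (!is.null(loss_fns)) loss_fns[[t]] else NULL
    tg <- if (is.null(lf)) targets[, , t] else NULL
    cfg_t <- cfg
    init_t <- if (warm) init[[t]] else if (t > 1L) prev else NULL
    if (t > 1L) {
      cfg_t$radius <- radii[t - 1L]
      # chained frames warm-start from the neighbour's solution; the joint
      # stage alone suffices there and keeps the schedule affordable
      if (!warm) {
        cfg_t$steps_tail <- 0L
        cfg_t$steps_proj <- 0L
      }
      res <- ilo_invert(gen, target = tg, cfg = cfg_t, init = init_t,
                        loss_fn = lf, ball_center = prev, crop = crop)
    } else {
      res <- ilo_invert(gen, target = tg, cfg = cfg_t, init = init_t,
                        loss_fn = lf, crop = crop)
    }
    out_lat[[t]] <- res$latents
    out_loss[t] <- res$loss
    prev <- res$latents
  }
  list(latents = out_lat, loss = out_loss)
}

#' Latent initialization by direct k-space data consistency
#'
#' Per frame, minimizes the measured-data discrepancy
#' `sum_c ||y_{c,t} - Omega_t F S_c (Phi_t * s * G(w_t))||^2` over the
#' latents (with the same l1-ball chaining as [invert_series()]), where
#' `Phi_t` is the external phase estimate and `s` the magnitude scale.
#' Used to initialize the outer loop of the parameter-mapping pathway.
#'
#' @param gen adapted `generator`
#' @param kspace a `kspace` object
#' @param Phi complex `N x Nt` unit-modulus phase maps
#' @param cfg an [inversion_config()]
#' @param scale scalar (or per-frame vector) mapping generator output to
#'   image magnitude units
#' @param init optional per-frame warm-start latents
#' @return list with `latents` and `loss` per frame
#' @export
latent_init_data_consistency <- function(gen, kspace, Phi, cfg = inversion_config(),
                                         scale = 1, init = NULL) {
  if (is.null(Phi)) stop("per-frame phase maps are required")
  em <- encoding_model(kspace$coils, kspace$mask, grid = kspace$grid)
  nx <- kspace$grid[1L]; ny <- kspace$grid[2L]
  Nt <- em$Nt
  if (length(scale) == 1L) scale <- rep(scale, Nt)
  loss_fns <- vector("list", Nt)
  for (t in seq_len(Nt)) {
    loss_fns[[t]] <- local({
      tt <- t
      keep <- em$mask$mask[tt, ]
      sc <- scale[tt]
      if (!any(keep)) {
        function(img) list(loss = 0, grad = matrix(0, nx, ny))
      } else {
        function(img) {
          m <- as.vector(img) * sc
          resid_ss <- 0
          gacc <- rep(0 + 0i, nx * ny)
          for (c in seq_len(em$Nc)) {
            k <- fft2c(matrix(em$coils$maps[c, ] * Phi[, tt] * m, nx, ny))
            k[, !keep] <- 0 + 0i
            r <- k - {
              yk <- kspace$samples[, , c, tt]
              yk[, !keep] <- 0 + 0i
              yk
            }
            resid_ss <- resid_ss + sum(Mod(r)^2)
            gacc <- gacc + Conj(em$coils$maps[c, ] * Phi[, tt]) * as.vector(ifft2c(r))
          }
          list(loss = resid_ss, grad = matrix(2 * sc * Re(gacc), nx, ny))
        }
      }
    })
  }
  crop <- if (gen$spec$resolution > nx || gen$spec$resolution > ny) c(nx, ny) else NULL
  invert_series(gen, cfg = cfg, init = init, loss_fns = loss_fns, crop = crop)
}
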