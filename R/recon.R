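# Conjugate gradients for Hermitian positive (semi)definite systems on
# complex N x R coefficient matrices. applyM must be linear and Hermitian.
cg_solve <- function(applyM, b, U0 = NULL, tol = 1e-8, maxit = 200L) {
  U <- if (is.null(U0)) b * 0 else U0
  r <- b - applyM(U)
  p <- r
  rs <- sum(Mod(r)^2)
  b2 <- sum(Mod(b)^2)
  if (b2 == 0) return(U * 0)
  for (it in seq_len(maxit)) {
    if (sqrt(rs / b2) < tol) break
    Mp <- applyM(p)
    alpha <- rs / Re(sum(Conj(p) * Mp))
    U <- U + alpha * p
    r <- r - alpha * Mp
    rs_new <- sum(Mod(r)^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  U
}

# weighted finite-difference normal operator applied column-wise to U:
# sum_d D_d^H (w_d * D_d U_r). weights: (nx, ny, 2) real, or NULL for unit.
fd_normal_cols <- function(U, grid, weights = NULL) {
  out <- U * 0
  for (r in seq_len(ncol(U))) {
    g <- finite_difference(matrix(U[, r], grid[1L], grid[2L]))
    if (!is.null(weights)) g <- g * weights
    out[, r] <- as.vector(fd_adjoint(g))
  }
  out
}

# l2,1 IRLS weights from the current series fit (shared across frames)
irls_weights <- function(U, V, grid, eps = 1e-6) {
  g <- finite_difference(U %*% V, grid = grid)
  d <- dim(g)
  m <- matrix(Mod(g)^2, prod(d[1:3]), d[4L])
  w <- 1 / sqrt(rowSums(m) + eps^2)
  array(w, d[1:3])
}

eval_objective_t2 <- function(em, y, U, V, anchors, lambda1, lambda2) {
  C <- U %*% V
  data <- sum(Mod(enc_forward_series(em, C) - y)^2)
  anc <- if (is.null(anchors)) 0 else sum(rep(lambda1, each = nrow(C)) * Mod(C - anchors)^2)
  sp <- if (lambda2 > 0) lambda2 * joint_sparsity_norm(finite_difference(C, grid = em$grid)) else 0
  c(data = data, anchor = anc, sparsity = sp, total = data + anc + sp)
}

#' Subspace reconstruction with joint-sparsity or edge-weighted regularization
#'
#' Solves `min_U ||y - A(UV)||^2 + lambda2 * R(UV)` by conjugate gradients,
#' with `R` either the l2,1 joint-sparsity norm of finite differences
#' (handled by iteratively reweighted least squares) or an edge-weighted
#' quadratic (single CG solve). This is the conventional subspace baseline
#' and the initializer of the generative-prior pathway.
#'
#' @param kspace a `kspace` object
#' @param basis a `temporal_basis`
#' @param lambda2 regularization weight (0 gives plain least squares)
#' @param type `"joint-sparsity"` (l2,1 IRLS) or `"edge"` (weighted l2)
#' @param edge_weights `(nx, ny, 2)` weights for `type = "edge"`
#' @param em optional prebuilt [encoding_model()] (e.g. with field map)
#' @param U0 warm start
#' @param n_irls IRLS passes (joint-sparsity only)
#' @param cg_tol,cg_maxit conjugate-gradient stopping rules
#' @return complex `N x R` coefficients; IRLS objective history in
#'   `attr(,"objective")`
#' @export
baseline_subspace <- function(kspace, basis, lambda2 = 1e-6,
                              type = c("joint-sparsity", "edge"),
                              edge_weights = NULL, em = NULL, U0 = NULL,
                              n_irls = 6L, cg_tol = 1e-8, cg_maxit = 200L) {
  type <- match.arg(type)
  V <- basis$V
  if (is.null(em))
    em <- encoding_model(kspace$coils, kspace$mask, fieldmap = kspace$fieldmap,
                         grid = kspace$grid, dwell_s = kspace$dwell_s)
  y <- kspace$samples
  b <- enc_adjoint(em, y, V)
  grid <- em$grid
  if (lambda2 == 0) {
    U <- cg_solve(function(U) enc_normal(em, U, V), b, U0, cg_tol, cg_maxit)
    attr(U, "objective") <- eval_objective_t2(em, y, U, V, NULL, NULL, 0)[["total"]]
    return(U)
  }
  if (type == "edge") {
    if (is.null(edge_weights)) stop("edge type needs edge_weights")
    w2 <- edge_weights^2
    U <- cg_solve(function(U) enc_normal(em, U, V) + lambda2 * fd_normal_cols(U, grid, w2),
                  b, U0, cg_tol, cg_maxit)
    attr(U, "objective") <- sum(Mod(enc_forward_series(em, U %*% V) - y)^2)
    return(U)
  }
  U <- if (is.null(U0)) cg_solve(function(U) enc_normal(em, U, V), b, NULL, cg_tol, 50L) else U0
  objs <- numeric(n_irls)
  for (k in seq_len(n_irls)) {
    w <- irls_weights(U, V, grid)
    U <- cg_solve(function(Uv) enc_normal(em, Uv, V) + (lambda2 / 2) * fd_normal_cols(Uv, grid, w),
                  b, U, cg_tol, cg_maxit)
    objs[k] <- eval_objective_t2(em, y, U, V, NULL, NULL, lambda2)[["total"]]
  }
  attr(U, "objective") <- objs
  U
}

#' Generative-anchored coefficient update for parameter mapping
#'
#' The convex subproblem of the alternating scheme: data consistency plus
#' per-frame anchors `Phi_t * G(w_t)` weighted by `lambda1[t]`, plus the
#' joint-sparsity term (IRLS), solved by conjugate gradients on the stacked
#' normal equations.
#'
#' @param kspace a `kspace` object
#' @param basis a `temporal_basis`
#' @param anchors complex `N x Nt` anchor frames (phase times generator output)
#' @param lambda1 per-frame anchor weights (length `Nt`)
#' @param lambda2 joint-sparsity weight
#' @param U0 warm start
#' @param em optional prebuilt encoding model
#' @param n_irls,cg_tol,cg_maxit solver controls
#' @return complex `N x R` coefficients with objective history attribute
#' @export
subproblem2_t2 <- function(kspace, basis, anchors, lambda1, lambda2 = 0,
                           U0 = NULL, em = NULL, n_irls = 4L,
                           cg_tol = 1e-8, cg_maxit = 200L) {
  V <- basis$V
  Nt <- ncol(V)
  if (length(lambda1) == 1L) lambda1 <- rep(lambda1, Nt)
  if (length(lambda1) != Nt) stop("lambda1 must have one weight per frame")
  if (any(lambda1 < 0) || lambda2 < 0) stop("regularization weights must be >= 0")
  if (is.null(em))
    em <- encoding_model(kspace$coils, kspace$mask, grid = kspace$grid)
  y <- kspace$samples
  grid <- em$grid
  Vh <- Conj(t(V))
  Panchor <- V %*% (lambda1 * Vh)                       # R x R
  b <- enc_adjoint(em, y, V) + anchors %*% (lambda1 * Vh)
  applyM0 <- function(U) enc_normal(em, U, V) + U %*% Panchor
  if (lambda2 == 0) {
    U <- cg_solve(applyM0, b, U0, cg_tol, cg_maxit)
    attr(U, "objective") <- eval_objective_t2(em, y, U, V, anchors, lambda1, 0)[["total"]]
    return(U)
  }
  U <- if (is.null(U0)) cg_solve(applyM0, b, NULL, cg_tol, 50L) else U0
  objs <- numeric(n_irls)
  for (k in seq_len(n_irls)) {
    w <- irls_weights(U, V, grid)
    U <- cg_solve(function(Uv) applyM0(Uv) + (lambda2 / 2) * fd_normal_cols(Uv, grid, w),
                  b, U, cg_tol, cg_maxit)
    objs[k] <- eval_objective_t2(em, y, U, V, anchors, lambda1, lambda2)[["total"]]
  }
  attr(U, "objective") <- objs
  U
}

#' Generative-anchored coefficient update for spectroscopic imaging
#'
#' Quadratic subproblem with per-coefficient anchors (magnitude-network times
#' phase-network products) and an edge-weighted finite-difference penalty;
#' the field-inhomogeneity phase is part of the encoding model.
#'
#' @param kspace a `kspace` object
#' @param basis a `temporal_basis`
#' @param anchors complex `N x R` anchor coefficient maps
#' @param lambda1 per-coefficient anchor weights (length `R` or scalar)
#' @param lambda2 edge-weighted regularization weight
#' @param edge_weights `(nx, ny, 2)` weights in `[0, 1]`
#' @param U0 warm start
#' @param em optional prebuilt encoding model (with field map)
#' @param cg_tol,cg_maxit solver controls
#' @return complex `N x R` coefficients
#' @export
subproblem2_mrsi <- function(kspace, basis, anchors, lambda1, lambda2 = 0,
                             edge_weights = NULL, U0 = NULL, em = NULL,
                             cg_tol = 1e-8, cg_maxit = 200L) {
  V <- basis$V
  R <- nrow(V)
  if (ncol(anchors) != R) stop("anchor count must equal the subspace rank")
  if (length(lambda1) == 1L) lambda1 <- rep(lambda1, R)
  if (length(lambda1) != R) stop("lambda1 must have one weight per coefficient")
  if (is.null(em))
    em <- encoding_model(kspace$coils, kspace$mask, fieldmap = kspace$fieldmap,
                         grid = kspace$grid, dwell_s = kspace$dwell_s)
  grid <- em$grid
  w2 <- if (!is.null(edge_weights)) edge_weights^2 else NULL
  b <- enc_adjoint(em, kspace$samples, V) + sweep(anchors, 2L, lambda1, "*")
  applyM <- function(U) {
    out <- enc_normal(em, U, V) + sweep(U, 2L, lambda1, "*")
    if (lambda2 > 0) out <- out + lambda2 * fd_normal_cols(U, grid, w2)
    out
  }
  cg_solve(applyM, b, U0, cg_tol, cg_maxit)
}

#' Per-frame phase maps from a baseline reconstruction
#'
#' `Phi_t = exp(i * angle(frame_t))`, unit modulus everywhere (zero voxels
#' get phase 1).
#'
#' @param C complex `N x Nt` series (e.g. `U0 %*% V`)
#' @return complex `N x Nt` unit-modulus matrix
#' @export
sos_phase_source <- function(C) {
  if (inherits(C, "image_series")) C <- C$data
  m <- Mod(C)
  Phi <- ifelse(m > 0, C / m, 1 + 0i)
  Phi
}

#' Reconstruction configuration
#'
#' Settings of the alternating minimization: subspace rank, outer iteration
#' count, regularization weights (with the published presets), inversion
#' budgets for the initialization and the warm-started outer refinements,
#' and the latent-ball and frozen-level rules.
#'
#' @param rank subspace order R
#' @param iters outer iterations (default 5; convergence is iteration-count
#'   based for determinism)
#' @param lambda1 anchor weights: a numeric vector/scalar, or a preset name
#'   `"proposed"` (flat 0.04) or `"gan-only"` (0.1 for the first ten of
#'   sixteen echoes, 0.2 after, scaled proportionally for other Nt)
#' @param lambda2 sparsity weight (default 2e-7, the full-method value)
#' @param init_lambda2 joint-sparsity weight of the initializing baseline
#' @param dc_init run the k-space data-consistency latent initialization
#' @param inv an [inversion_config()] for the initial staged inversions
#' @param refine_steps joint-refinement steps per frame in later outer
#'   iterations (warm-started)
#' @param radius l1-ball chaining radius (`NULL` for the 0.1 * ||w_1||_1
#'   default)
#' @param frozen_levels latent levels kept fixed during inversion
#' @param norm_quantile quantile of the sum-of-squares reference that maps
#'   image magnitudes onto the generator's output range
#' @return a `recon_config` object
#' @export
recon_config <- function(rank, iters = 5L, lambda1 = "proposed", lambda2 = 2e-7,
                         init_lambda2 = 1e-6, dc_init = TRUE,
                         inv = inversion_config(steps_tail = 80L, steps_proj = 60L,
                                                steps_joint = 60L),
                         refine_steps = 40L, radius = NULL,
                         frozen_levels = integer(0), norm_quantile = 0.97) {
  if (iters < 1L) stop("iters must be >= 1")
  if (is.numeric(lambda1) && any(lambda1 < 0)) stop("lambda1 must be >= 0")
  if (lambda2 < 0) stop("lambda2 must be >= 0")
  structure(list(rank = as.integer(rank), iters = as.integer(iters),
                 lambda1 = lambda1, lambda2 = lambda2,
                 init_lambda2 = init_lambda2, dc_init = dc_init, inv = inv,
                 refine_steps = as.integer(refine_steps), radius = radius,
                 frozen_levels = as.integer(frozen_levels),
                 norm_quantile = norm_quantile),
            class = "recon_config")
}

lambda1_weights <- function(lambda1, Nt) {
  if (is.numeric(lambda1)) {
    if (length(lambda1) == 1L) return(rep(lambda1, Nt))
    if (length(lambda1) != Nt) stop("lambda1 length must match the frame count")
    return(lambda1)
  }
  switch(match.arg(lambda1, c("proposed", "gan-only")),
         "proposed" = rep(0.04, Nt),
         "gan-only" = {
           cut <- round(Nt * 10 / 16)
           c(rep(0.1, cut), rep(0.2, Nt - cut))
         })
}

#' Alternating minimization with subspace, generative and sparsity constraints
#'
#' The outer loop of the reconstruction: Subproblem I inverts the adapted
#' generator against the current frames (parameter mapping) or coefficient
#' maps (spectroscopic imaging) under chained l1-ball latent constraints;
#' Subproblem II updates the spatial coefficients by the convex
#' generative-anchored subspace solve. The parameter-mapping pathway is
#' initialized by a mildly sparsity-regularized baseline followed by direct
#' k-space data-consistency latent fitting; the spectroscopic pathway starts
#' from an edge-regularized baseline and freezes the finest latent level.
#'
#' @param application `"t2"` or `"mrsi"`
#' @param kspace a `kspace` object
#' @param basis a `temporal_basis`
#' @param gen adapted `generator` (T2), or `list(mag = , phase = )` (MRSI)
#' @param cfg a [recon_config()]
#' @param truth optional complex `N x Nt` ground-truth series for error
#'   tracking
#' @param reference reference image for edge weights (MRSI)
#' @param U0 optional precomputed initializing baseline coefficients
#' @param init_latents optional precomputed per-frame latent stacks (skips
#'   the data-consistency initialization)
#' @param verbose print per-iteration objective terms
#' @return a `recon_state`: final `U`, `V`, `series`, latents and a
#'   per-iteration `history` data frame
#' @export
alternate_recon <- function(application = c("t2", "mrsi"), kspace, basis, gen,
                            cfg, truth = NULL, reference = NULL, U0 = NULL,
                            init_latents = NULL, verbose = FALSE) {
  application <- match.arg(application)
  if (application == "t2") {
    if (!inherits(gen, "generator")) stop("run adaptation first: an adapted generator is required")
    alternate_t2(kspace, basis, gen, cfg, truth, verbose, U0 = U0,
                 init_latents = init_latents)
  } else {
    if (!is.list(gen) || !inherits(gen$mag, "generator") || !inherits(gen$phase, "generator"))
      stop("run adaptation first: adapted magnitude and phase generators are required")
    alternate_mrsi(kspace, basis, gen, cfg, truth, reference, verbose)
  }
}

alternate_t2 <- function(kspace, basis, gen, cfg, truth = NULL, verbose = FALSE,
                         U0 = NULL, init_latents = NULL) {
  V <- basis$V
  Nt <- ncol(V)
  grid <- kspace$grid
  nx <- grid[1L]; ny <- grid[2L]
  lambda1 <- lambda1_weights(cfg$lambda1, Nt)
  em <- encoding_model(kspace$coils, kspace$mask, grid = grid)
  y <- kspace$samples
  # initialization: mild joint-sparsity baseline, fixed phase, magnitude scale
  U <- if (is.null(U0)) baseline_subspace(kspace, basis, lambda2 = cfg$init_lambda2, em = em) else U0
  Phi <- sos_phase_source(U %*% V)
  # per-frame magnitude scales keep every inversion target in the
  # generator's trained intensity range regardless of echo decay
  frame_scales <- function(C) {
    s <- apply(Mod(C), 2L, stats::quantile, probs = cfg$norm_quantile, names = FALSE)
    s[s <= 0] <- max(s, 1)
    s
  }
  scale <- frame_scales(U %*% V)
  crop <- if (gen$spec$resolution > nx) c(nx, ny) else NULL
  skip_gan <- all(lambda1 == 0) ||
    (cfg$inv$steps_tail + cfg$inv$steps_proj + cfg$inv$steps_joint + cfg$refine_steps) == 0L
  lat <- init_latents
  if (is.null(lat) && !skip_gan && cfg$dc_init) {
    icfg <- cfg$inv
    icfg$radius <- cfg$radius
    icfg$frozen_levels <- cfg$frozen_levels
    dc <- latent_init_data_consistency(gen, kspace, Phi, icfg, scale = scale)
    lat <- dc$latents
  }
  hist <- vector("list", cfg$iters)
  for (i in seq_len(cfg$iters)) {
    anchors <- NULL
    if (!skip_gan) {
      C <- U %*% V
      scale <- frame_scales(C)
      targets <- array(sweep(Mod(C), 2L, scale, "/"), c(nx, ny, Nt))
      icfg <- cfg$inv
      icfg$radius <- cfg$radius
      icfg$frozen_levels <- cfg$frozen_levels
      if (!is.null(lat)) {       # warm start: joint refinement only
        icfg$steps_tail <- 0L
        icfg$steps_proj <- 0L
        icfg$steps_joint <- cfg$refine_steps
      }
      inv <- invert_series(gen, targets, icfg, init = lat, crop = crop)
      lat <- inv$latents
      G <- vapply(lat, function(w) as.vector(synth_crop(gen, w, crop)), numeric(nx * ny))
      anchors <- Phi * sweep(G, 2L, scale, "*")
      U <- subproblem2_t2(kspace, basis, anchors, lambda1, cfg$lambda2, U0 = U, em = em)
    } else {
      U <- if (cfg$lambda2 > 0)
        baseline_subspace(kspace, basis, lambda2 = cfg$lambda2, em = em, U0 = U)
      else baseline_subspace(kspace, basis, lambda2 = 0, em = em, U0 = U)
    }
    obj <- eval_objective_t2(em, y, U, V, anchors,
                             if (is.null(anchors)) NULL else lambda1, cfg$lambda2)
    err <- if (!is.null(truth)) relative_l2(U %*% V, truth) else NA_real_
    hist[[i]] <- data.frame(iter = i, obj_data = obj[["data"]],
                            obj_anchor = obj[["anchor"]],
                            obj_sparsity = obj[["sparsity"]],
                            obj_total = obj[["total"]], rel_err_pct = err)
    if (verbose)
      message(sprintf("iter %d: data %.4g anchor %.4g sparse %.4g err %.3f%%",
                      i, obj[["data"]], obj[["anchor"]], obj[["sparsity"]], err))
  }
  structure(list(U = U, V = V, series = U %*% V, latents = lat, grid = grid,
                 scale = scale, Phi = Phi, history = do.call(rbind, hist),
                 application = "t2"),
            class = "recon_state")
}

alternate_mrsi <- function(kspace, basis, gens, cfg, truth = NULL,
                           reference = NULL, verbose = FALSE) {
  V <- basis$V
  R <- nrow(V)
  grid <- kspace$grid
  nx <- grid[1L]; ny <- grid[2L]
  em <- encoding_model(kspace$coils, kspace$mask, fieldmap = kspace$fieldmap,
                       grid = grid, dwell_s = kspace$dwell_s)
  if (is.null(reference)) stop("the spectroscopic pathway needs a reference image for edge weights")
  ew <- edge_weights_from_reference(reference)
  U <- baseline_subspace(kspace, basis, lambda2 = cfg$init_lambda2, type = "edge",
                         edge_weights = ew, em = em)
  lambda1 <- lambda1_weights(if (is.character(cfg$lambda1)) 1.6 else cfg$lambda1, R)
  crop <- if (gens$mag$spec$resolution > nx) c(nx, ny) else NULL
  lat_m <- NULL; lat_p <- NULL
  hist <- vector("list", cfg$iters)
  for (i in seq_len(cfg$iters)) {
    scales <- apply(Mod(U), 2L, function(v) stats::quantile(v, cfg$norm_quantile, names = FALSE))
    scales[scales <= 0] <- 1
    anchors <- matrix(0 + 0i, nx * ny, R)
    new_m <- vector("list", R); new_p <- vector("list", R)
    for (r in seq_len(R)) {
      Tr <- matrix(U[, r] / scales[r], nx, ny)
      icfg <- cfg$inv
      icfg$frozen_levels <- union(cfg$frozen_levels, gens$mag$spec$levels)
      if (!is.null(lat_m)) {
        icfg$steps_tail <- 0L; icfg$steps_proj <- 0L
        icfg$steps_joint <- cfg$refine_steps
      }
      # alternate magnitude- and phase-network latent updates
      wm <- if (!is.null(lat_m)) lat_m[[r]] else NULL
      wp <- if (!is.null(lat_p)) lat_p[[r]] else NULL
      cur_phase <- if (is.null(wp)) matrix(0, nx, ny) else
        synth_crop(gens$phase, wp, crop)
      for (pass in 1:2) {
        lf_m <- local({
          ph <- cur_phase
          function(img) {
            tgt <- Re(Conj(exp(1i * ph)) * Tr)
            r_ <- img - tgt
            list(loss = sum(r_^2), grad = 2 * r_)
          }
        })
        rm_ <- ilo_invert(gens$mag, cfg = icfg, init = wm, loss_fn = lf_m, crop = crop)
        wm <- rm_$latents
        mag <- synth_crop(gens$mag, wm, crop)
        lf_p <- local({
          mg <- mag
          function(ph) {
            rr <- mg * exp(1i * ph) - Tr
            list(loss = sum(Mod(rr)^2), grad = -2 * mg * Im(exp(1i * ph) * Conj(rr)))
          }
        })
        rp_ <- ilo_invert(gens$phase, cfg = icfg, init = wp, loss_fn = lf_p, crop = crop)
        wp <- rp_$latents
        cur_phase <- synth_crop(gens$phase, wp, crop)
      }
      new_m[[r]] <- wm; new_p[[r]] <- wp
      anchors[, r] <- scales[r] * as.vector(synth_crop(gens$mag, wm, crop) * exp(1i * cur_phase))
    }
    lat_m <- new_m; lat_p <- new_p
    U <- subproblem2_mrsi(kspace, basis, anchors, lambda1, cfg$lambda2,
                          edge_weights = ew, U0 = U, em = em)
    err <- if (!is.null(truth)) relative_l2(U %*% V, truth) else NA_real_
    data_obj <- sum(Mod(enc_forward_series(em, U %*% V) - kspace$samples)^2)
    hist[[i]] <- data.frame(iter = i, obj_data = data_obj, rel_err_pct = err)
    if (verbose) message(sprintf("iter %d: data %.4g err %.3f%%", i, data_obj, err))
  }
  structure(list(U = U, V = V, series = U %*% V, latents_mag = lat_m,
                 latents_phase = lat_p, grid = grid,
                 history = do.call(rbind, hist), application = "mrsi"),
            class = "recon_state")
}
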