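#' Synthetic brain-like tissue phantom
#'
#' Builds a label map of nested smooth elliptical/blob structures on an
#' `nx x ny` grid with per-label proton density, T2 and (for spectroscopic
#' phantoms) a small set of Lorentzian line parameters. Label 0 is the
#' background outside the object; labels 1..n_structures are tissue
#' compartments (label 1 is the outer "head" ellipse).
#'
#' @param seed RNG seed; the model is a pure function of its arguments
#' @param grid integer pair `(nx, ny)`, both at least 32
#' @param n_structures number of tissue labels (>= 1)
#' @param heterogeneity relative amplitude of smooth within-tissue variation
#'   of proton density and T2 (0 gives exactly piecewise-constant tissue and
#'   an exactly low-rank echo series; the accelerated benchmark uses 0.15 to
#'   emulate the parameter continuum of real tissue)
#' @return a `tissue_model` object
#' @export
make_tissue_model <- function(seed = 0L, grid = c(64L, 64L), n_structures = 4L,
                              heterogeneity = 0) {
  nx <- as.integer(grid[1L]); ny <- as.integer(grid[2L])
  if (nx < 32L || ny < 32L) stop("grid too small: both dimensions must be >= 32")
  if (n_structures < 1L) stop("n_structures must be >= 1")
  set.seed(seed)
  xs <- seq(-1, 1, length.out = nx)
  ys <- seq(-1, 1, length.out = ny)
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  lab <- matrix(0L, nx, ny)
  # outer head ellipse, slightly randomized
  a0 <- stats::runif(1, 0.78, 0.88); b0 <- stats::runif(1, 0.70, 0.82)
  lab[(X / a0)^2 + (Y / b0)^2 <= 1] <- 1L
  # interior blobs: rotated ellipses perturbed by a smooth angular wobble
  for (k in seq_len(n_structures - 1L) + 1L) {
    cx <- stats::runif(1, -0.35, 0.35); cy <- stats::runif(1, -0.35, 0.35)
    a <- stats::runif(1, 0.12, 0.38); b <- stats::runif(1, 0.10, 0.32)
    th <- stats::runif(1, 0, pi)
    w1 <- stats::runif(1, 0.0, 0.15); ph <- stats::runif(1, 0, 2 * pi)
    Xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    Yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    ang <- atan2(Yr, Xr)
    r2 <- (Xr / a)^2 + (Yr / b)^2
    inside <- r2 <= (1 + w1 * cos(3 * ang + ph))^2 & lab >= 1L
    lab[inside] <- k
  }
  L <- n_structures
  pd <- c(0, stats::runif(L, 0.55, 1.0))
  t2 <- c(NA_real_, stats::runif(L, 40, 250))
  # spectral line triplets (shared frequencies, label-dependent amplitudes)
  freqs <- c(0, 120, 260)
  amps <- rbind(rep(0, 3), matrix(stats::runif(L * 3, 0.1, 1.0), L, 3))
  lws <- rbind(rep(20, 3), matrix(stats::runif(L * 3, 8, 25), L, 3))
  pd_map <- matrix(pd[lab + 1L], nx, ny)
  t2_map <- matrix(t2[lab + 1L], nx, ny)
  if (heterogeneity > 0) {
    f1 <- poly_phase(c(nx, ny), stats::runif(6, -1, 1))
    f2 <- poly_phase(c(nx, ny), stats::runif(6, -1, 1))
    f1 <- f1 / max(abs(f1)); f2 <- f2 / max(abs(f2))
    pd_map <- pd_map * (1 + heterogeneity * f1)
    t2_map <- t2_map * (1 + heterogeneity * f2)
  }
  structure(list(label_map = lab, grid = c(nx, ny), n_labels = L + 1L,
                 pd = pd, t2_ms = t2, pd_map = pd_map, t2_map = t2_map,
                 heterogeneity = heterogeneity,
                 spec_freq_hz = freqs, spec_amp = amps, spec_lw_hz = lws,
                 seed = as.integer(seed)),
            class = "tissue_model")
}

# smooth low-order polynomial phase map in radians
poly_phase <- function(grid, coef) {
  nx <- grid[1L]; ny <- grid[2L]
  x <- seq(-1, 1, length.out = nx); y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  coef[1L] + coef[2L] * X + coef[3L] * Y + coef[4L] * X * Y +
    coef[5L] * X^2 + coef[6L] * Y^2
}

new_image_series <- function(data, grid, frame_axis, attrs = list()) {
  structure(c(list(data = data, grid = grid, frame_axis = frame_axis), attrs),
            class = "image_series")
}

#' Multi-echo spin-echo image series with mono-exponential decay
#'
#' Every voxel decays as `PD * exp(-TE/T2)`; a fixed smooth polynomial phase
#' map plus a small per-echo global phase make the series complex while
#' preserving the exact low rank (one rank per distinct T2 value).
#'
#' @param model a [make_tissue_model()] phantom
#' @param te_schedule echo times in ms, all positive
#' @return an `image_series` (complex `N x Nt` Casorati data plus grid info)
#' @export
simulate_t2_series <- function(model, te_schedule) {
  stopifnot(inherits(model, "tissue_model"))
  if (length(te_schedule) < 1L) stop("te_schedule must not be empty")
  if (any(te_schedule <= 0)) stop("all echo times must be positive")
  pd <- as.vector(model$pd_map)
  t2 <- as.vector(model$t2_map)
  pd[is.na(pd)] <- 0
  t2[is.na(t2) | t2 <= 0] <- Inf
  set.seed(model$seed + 101L)
  ph0 <- as.vector(poly_phase(model$grid, stats::runif(6, -0.6, 0.6)))
  gph <- 0.05 * seq_along(te_schedule) / length(te_schedule)  # per-echo global phase
  N <- length(pd); Nt <- length(te_schedule)
  C <- matrix(0 + 0i, N, Nt)
  for (t in seq_len(Nt)) {
    C[, t] <- pd * exp(-te_schedule[t] / t2) * exp(1i * (ph0 + gph[t]))
  }
  new_image_series(C, model$grid, "echo", list(te_ms = te_schedule, model_seed = model$seed))
}

#' Smooth field-inhomogeneity map
#'
#' Low-order polynomial off-resonance map (Hz) used to form the unit-modulus
#' phase operator `exp(i 2 pi df(x) t)` of spectroscopic encoding.
#'
#' @param seed RNG seed
#' @param grid `(nx, ny)`
#' @param max_hz approximate peak off-resonance in Hz
#' @return a `field_map` object (matrix of Hz values)
#' @export
make_field_map <- function(seed = 0L, grid = c(64L, 64L), max_hz = 20) {
  set.seed(seed + 211L)
  f <- poly_phase(grid, stats::runif(6, -1, 1))
  f <- f / max(abs(f)) * max_hz
  structure(list(df_hz = matrix(f, grid[1L], grid[2L]), grid = grid), class = "field_map")
}

#' Spatiospectral (MRSI-like) image series
#'
#' Each voxel's FID is a sum of damped complex exponentials (Lorentzian
#' lines) with label-wise amplitudes; the series is exactly partially
#' separable with rank at most the number of distinct tissue labels. The
#' field-inhomogeneity phase lives in the encoding operator, not in the
#' returned series; the supplied `fieldmap` is attached for the simulator.
#' The ground-truth temporal basis is the SVD of the noiseless series.
#'
#' @param model a [make_tissue_model()] phantom
#' @param n_fid number of FID samples (>= twice the number of lines)
#' @param bandwidth spectral bandwidth in Hz (positive)
#' @param fieldmap optional [make_field_map()] result
#' @return list with `series` (an `image_series`, dwell time attached) and
#'   `basis` (ground-truth `temporal_basis`)
#' @export
simulate_mrsi_series <- function(model, n_fid = 150L, bandwidth = 1670,
                                 fieldmap = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  K <- length(model$spec_freq_hz)
  if (n_fid < 2L * K) stop("n_fid must be at least twice the number of spectral lines")
  dt <- 1 / bandwidth
  tk <- (seq_len(n_fid) - 1L) * dt
  lab <- as.vector(model$label_map)
  N <- length(lab)
  # per-label FID profiles
  prof <- matrix(0 + 0i, model$n_labels, n_fid)
  for (li in seq_len(model$n_labels)) {
    for (k in seq_len(K)) {
      prof[li, ] <- prof[li, ] + model$spec_amp[li, k] *
        exp((2i * pi * model$spec_freq_hz[k] - pi * model$spec_lw_hz[li, k]) * tk)
    }
  }
  C <- prof[lab + 1L, , drop = FALSE] * model$pd[lab + 1L]
  sv <- svd(C)
  tol <- 1e-8 * sv$d[1L]
  R <- max(1L, sum(sv$d > tol))
  V <- t(Conj(sv$v[, seq_len(R), drop = FALSE]))
  series <- new_image_series(C, model$grid, "fid",
                             list(dwell_s = dt, bandwidth_hz = bandwidth,
                                  fieldmap = fieldmap, model_seed = model$seed))
  list(series = series,
       basis = new_temporal_basis(V, provenance = "truth-SVD"))
}

#' Smooth complex coil sensitivity maps
#'
#' Complex low-order polynomial sensitivities, normalized to unit
#' root-sum-of-squares at every voxel so the SENSE normal operator is well
#' scaled without an external calibration.
#'
#' @param seed RNG seed
#' @param grid `(nx, ny)`
#' @param n_coils number of coils (>= 1)
#' @return a `coil_maps` object (`Nc x N` complex matrix plus grid)
#' @export
make_coil_maps <- function(seed = 0L, grid = c(64L, 64L), n_coils = 4L) {
  if (n_coils < 1L) stop("n_coils must be >= 1")
  set.seed(seed + 431L)
  nx <- grid[1L]; ny <- grid[2L]
  N <- nx * ny
  maps <- matrix(0 + 0i, n_coils, N)
  for (c in seq_len(n_coils)) {
    re <- poly_phase(grid, stats::runif(6, -1, 1)) + 1.2
    im <- poly_phase(grid, stats::runif(6, -1, 1))
    maps[c, ] <- as.vector(re) + 1i * as.vector(im)
  }
  rss <- sqrt(colSums(Mod(maps)^2))
  rss[rss == 0] <- 1
  maps <- sweep(maps, 2L, rss, "/")
  structure(list(maps = maps, grid = grid, n_coils = n_coils), class = "coil_maps")
}

#' 1D-random Cartesian sampling mask with navigator lines
#'
#' Phase-encode (ky) undersampling: a centered navigator block is sampled at
#' every frame; the first frame additionally samples a wider fully-sampled
#' center block; remaining lines are drawn uniformly at random so that the
#' per-frame sampled-line count is `round(ny / AF)` (within one line).
#'
#' @param seed RNG seed
#' @param AF acceleration factor (>= 1)
#' @param n_center_nav navigator block width (>= 2), sampled at all frames
#' @param n_center_first_frame center block width fully sampled at frame 1
#' @param Nt number of frames
#' @param ny number of phase encodes
#' @return a `sampling_mask` object (logical `Nt x ny` matrix)
#' @export
make_mask <- function(seed = 0L, AF = 4, n_center_nav = 12L,
                      n_center_first_frame = 48L, Nt = 16L, ny = 192L) {
  if (AF < 1) stop("AF must be >= 1")
  if (n_center_nav < 2L) stop("n_center_nav must be >= 2")
  set.seed(seed + 877L)
  center_block <- function(w) {
    lo <- floor(ny / 2) - floor(w / 2) + 1L
    seq(lo, lo + w - 1L)
  }
  nav <- center_block(min(n_center_nav, ny))
  first_center <- center_block(min(n_center_first_frame, ny))
  target <- max(length(nav), as.integer(round(ny / AF)))
  m <- matrix(FALSE, Nt, ny)
  for (t in seq_len(Nt)) {
    lines <- nav
    if (t == 1L) lines <- union(lines, first_center)
    need <- target - length(lines)
    if (need > 0L) {
      pool <- setdiff(seq_len(ny), lines)
      lines <- c(lines, sample(pool, min(need, length(pool))))
    }
    m[t, lines] <- TRUE
  }
  structure(list(mask = m, AF = AF, n_center_nav = length(nav),
                 nav_lines = nav, first_center = first_center,
                 Nt = Nt, ny = ny), class = "sampling_mask")
}

#' Simulate undersampled multi-coil k-space
#'
#' Applies the SENSE encoding operator (coil weighting, unitary centered 2D
#' FFT, phase-encode sampling, optional field-inhomogeneity phase) to the
#' image series and adds i.i.d. complex Gaussian noise at the sampled
#' locations only.
#'
#' @param series an `image_series`
#' @param coils a `coil_maps` object on the same grid
#' @param mask a `sampling_mask` with `Nt` rows matching the series
#' @param noise_sigma complex noise standard deviation (per sampled entry;
#'   real and imaginary parts each get `noise_sigma / sqrt(2)`)
#' @param seed RNG seed for the noise realization
#' @return a `kspace` object: zero-filled `nx x ny x Nc x Nt` complex array,
#'   the mask, coils and the noise level used
#' @export
simulate_kspace <- function(series, coils, mask, noise_sigma = 0, seed = 0L) {
  stopifnot(inherits(series, "image_series"), inherits(coils, "coil_maps"),
            inherits(mask, "sampling_mask"))
  if (!all(series$grid == coils$grid)) stop("coil/series grid mismatch")
  Nt <- ncol(series$data)
  if (mask$Nt != Nt) stop("mask frame count does not match the series")
  if (mask$ny != series$grid[2L]) stop("mask ny does not match the series grid")
  em <- encoding_model(coils, mask, fieldmap = attr_fieldmap(series), grid = series$grid,
                       dwell_s = series$dwell_s)
  y <- enc_forward_series(em, series$data)
  if (noise_sigma > 0) {
    set.seed(seed + 1543L)
    sel <- which(sampling_weights(em) > 0)
    n <- length(sel)
    for (c in seq_len(coils$n_coils)) {
      noise <- complex(real = stats::rnorm(n, sd = noise_sigma / sqrt(2)),
                       imaginary = stats::rnorm(n, sd = noise_sigma / sqrt(2)))
      yc <- y[, , c, , drop = FALSE]
      dim(yc) <- c(prod(series$grid), Nt)
      yc[sel] <- yc[sel] + noise
      dim(yc) <- c(series$grid[1L], series$grid[2L], 1L, Nt)
      y[, , c, ] <- yc
    }
  }
  structure(list(samples = y, mask = mask, coils = coils, grid = series$grid,
                 noise_sigma = noise_sigma,
                 te_ms = series$te_ms, dwell_s = series$dwell_s,
                 fieldmap = attr_fieldmap(series), seed = as.integer(seed)),
            class = "kspace")
}

attr_fieldmap <- function(series) series$fieldmap

#' Sum-of-squares reference image
#'
#' `sqrt(sum_t |rho_t|^2)` per voxel across frames; the subject-specific
#' reference used for generator adaptation.
#'
#' @param series an `image_series` or complex `N x Nt` matrix
#' @return a real `nx x ny` matrix (nonnegative)
#' @export
sos_reference <- function(series) {
  C <- if (inherits(series, "image_series")) series$data else series
  grid <- if (inherits(series, "image_series")) series$grid else NULL
  r <- sqrt(rowSums(Mod(C)^2))
  if (!is.null(grid)) matrix(r, grid[1L], grid[2L]) else r
}
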