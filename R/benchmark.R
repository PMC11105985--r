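# Standard synthetic study conditions used by the examples, tests and the
# reproduction script: a 48x48, 16-echo multi-spin-echo phantom (echo spacing
# 8.8 ms), 4 coils, 1D-random undersampling with a 4-line navigator block and
# a 12-line fully sampled center at the first echo (the published 12/48-line
# blocks scaled from 192 to 48 phase encodes), and 1% complex measurement
# noise. The generator prior is pretrained once on a corpus of phantom
# contrast images and adapted per subject to the sum-of-squares reference of
# an initial subspace reconstruction.

#' Corpus of phantom contrast images for generator pretraining
#'
#' Random tissue phantoms rendered at random echo times, magnitude-normalized
#' to `[0, 1]`: the stand-in for a population image database.
#'
#' @param n_images corpus size
#' @param resolution image size (generator resolution)
#' @param seed RNG seed
#' @return array `resolution x resolution x n_images`
#' @export
phantom_corpus <- function(n_images = 300L, resolution = 64L, seed = 0L) {
  out <- array(0, c(resolution, resolution, n_images))
  for (i in seq_len(n_images)) {
    set.seed(seed * 100003L + i)
    ns <- sample(3:5, 1L)
    te <- stats::runif(1, 8, 150)
    model <- make_tissue_model(seed = seed * 100003L + i, grid = c(resolution, resolution),
                               n_structures = ns, heterogeneity = 0.15)
    img <- Mod(matrix(simulate_t2_series(model, te)$data, resolution, resolution))
    mx <- max(img)
    if (mx > 0) img <- img / mx
    out[, , i] <- img
  }
  out
}

#' Corpus of smooth phase images for phase-generator pretraining
#'
#' Low-order polynomial phase maps in (-pi, pi), emulating the smooth phase
#' of coil-combined images.
#'
#' @param n_images corpus size
#' @param resolution image size
#' @param seed RNG seed
#' @return array `resolution x resolution x n_images`
#' @export
phase_corpus <- function(n_images = 300L, resolution = 64L, seed = 0L) {
  out <- array(0, c(resolution, resolution, n_images))
  for (i in seq_len(n_images)) {
    set.seed(seed * 99991L + i)
    out[, , i] <- poly_phase(c(resolution, resolution), stats::runif(6, -1.2, 1.2))
  }
  out
}

#' Simulate the standard multi-echo parameter-mapping benchmark
#'
#' @param seed phantom/noise seed
#' @param AF acceleration factor
#' @param grid voxel grid (default 48 x 48)
#' @param n_echoes echoes, TE = 8.8, 17.6, ... ms
#' @param n_coils coils
#' @param rank subspace order for the navigator-estimated basis
#' @param noise_pct complex noise level as a percent of the RMS sampled
#'   k-space signal
#' @return list with `kspace`, `basis` (navigator SVD), `truth` (complex
#'   series), `te_ms`, `grid`, `model`, `noise_sigma`
#' @export
t2_benchmark_data <- function(seed = 1L, AF = 4, grid = c(48L, 48L),
                              n_echoes = 16L, n_coils = 4L, rank = 3L,
                              noise_pct = 1) {
  te <- 8.8 * seq_len(n_echoes)
  model <- make_tissue_model(seed = seed, grid = grid, n_structures = 4L,
                             heterogeneity = 0.15)
  series <- simulate_t2_series(model, te)
  coils <- make_coil_maps(seed = seed, grid = grid, n_coils = n_coils)
  ny <- grid[2L]
  nav <- max(4L, 2L * round(ny * 12 / 192 / 2))
  first_center <- max(nav, 2L * round(ny * 48 / 192 / 2))
  mask <- make_mask(seed = seed, AF = AF, n_center_nav = nav,
                    n_center_first_frame = first_center,
                    Nt = n_echoes, ny = ny)
  y0 <- simulate_kspace(series, coils, mask, noise_sigma = 0)
  m_sampled <- sum(sampling_weights(encoding_model(coils, mask, grid = grid))) * n_coils
  sigma <- noise_pct / 100 * sqrt(sum(Mod(y0$samples)^2) / m_sampled)
  ks <- simulate_kspace(series, coils, mask, noise_sigma = sigma, seed = seed)
  basis <- estimate_basis(ks, rank = rank)
  list(kspace = ks, basis = basis, truth = series$data, te_ms = te,
       grid = grid, model = model, noise_sigma = sigma)
}

#' One-call subject-specific adaptation
#'
#' Runs reference inversion followed by a single parameter-adaptation pass.
#'
#' @param gen pretrained `generator`
#' @param reference reference image, rescaled internally to `[0, 1]`
#' @param alpha deviation penalty
#' @param inv_cfg inversion budget for the reference inversion
#' @param adapt_steps parameter-update steps
#' @return an `adaptation_result` (with `scale` used for normalization)
#' @export
adapt_to_reference <- function(gen, reference,
                               alpha = 0.001,
                               inv_cfg = inversion_config(steps_tail = 80L,
                                                          steps_proj = 60L,
                                                          steps_joint = 60L),
                               adapt_steps = 4000L) {
  mx <- max(reference)
  # keep the native grid: losses act on the central crop of the generator
  # output, so the out-of-grid border stays unconstrained
  xp <- if (mx > 0) reference / mx else reference
  wp <- invert_reference(gen, xp, inv_cfg)
  ad <- adapt_parameters(gen, wp$latents, xp, alpha = alpha, steps = adapt_steps)
  ad$reference <- xp
  ad$scale <- mx
  ad
}

#' Benchmark reconstruction methods
#'
#' Returns the four standard pipelines as closures for [sweep_report()]:
#' plain subspace least squares, subspace + joint sparsity, subspace + the
#' generative anchor alone (two-tier per-echo weights), and the full method
#' (flat anchors plus mild joint sparsity).
#'
#' @param prior pretrained `generator` (adapted per call to the data's own
#'   sum-of-squares reference)
#' @param rank subspace order
#' @param iters outer iterations for the generative pathways
#' @param inv_cfg staged-inversion budget for the data-consistency
#'   initialization
#' @param refine_steps warm-start refinement steps per frame per iteration
#' @param adapt_steps parameter-adaptation budget
#' @return named list of method closures
#' @export
t2_method_suite <- function(prior, rank = 3L, iters = 5L,
                            inv_cfg = inversion_config(steps_tail = 60L,
                                                       steps_proj = 40L,
                                                       steps_joint = 40L),
                            refine_steps = 12L, adapt_steps = 600L,
                            cache = NULL) {
  adapt_cache <- cache %||% new.env(parent = emptyenv())
  get_adapted <- function(kspace, basis) {
    key <- paste0("s", kspace$seed, "af", kspace$mask$AF)
    if (!is.null(adapt_cache[[key]])) return(adapt_cache[[key]])
    U0 <- baseline_subspace(kspace, basis, lambda2 = 1e-6)
    sos <- matrix(sos_reference(U0 %*% basis$V), kspace$grid[1L], kspace$grid[2L])
    ad <- adapt_to_reference(prior, sos, inv_cfg = inv_cfg, adapt_steps = adapt_steps)
    ad$U0 <- U0
    adapt_cache[[key]] <- ad
    ad
  }
  run_gan <- function(kspace, basis, lambda1, lambda2, truth = NULL) {
    ad <- get_adapted(kspace, basis)
    cfg <- recon_config(rank = nrow(basis$V), iters = iters, lambda1 = lambda1,
                        lambda2 = lambda2, inv = inv_cfg, refine_steps = refine_steps)
    # the data-consistency latent initialization is method-independent:
    # compute it once per dataset and share it across the anchored methods
    dc_key <- paste0("dc_s", kspace$seed, "af", kspace$mask$AF)
    if (is.null(adapt_cache[[dc_key]])) {
      V <- basis$V
      Phi <- sos_phase_source(ad$U0 %*% V)
      scales <- apply(Mod(ad$U0 %*% V), 2L, stats::quantile, probs = 0.97, names = FALSE)
      scales[scales <= 0] <- max(scales, 1)
      adapt_cache[[dc_key]] <- latent_init_data_consistency(ad$gen, kspace, Phi,
                                                            inv_cfg, scale = scales)$latents
    }
    alternate_recon("t2", kspace, basis, ad$gen, cfg, truth = truth, U0 = ad$U0,
                    init_latents = adapt_cache[[dc_key]])
  }
  list(
    subspace = function(kspace, basis, truth = NULL)
      baseline_subspace(kspace, basis, lambda2 = 0) %*% basis$V,
    `subspace+sparsity` = function(kspace, basis, truth = NULL)
      baseline_subspace(kspace, basis, lambda2 = 1e-6) %*% basis$V,
    `subspace+gan` = function(kspace, basis, truth = NULL)
      run_gan(kspace, basis, "gan-only", 0, truth),
    proposed = function(kspace, basis, truth = NULL)
      run_gan(kspace, basis, "proposed", 2e-7, truth)
  )
}

#' Simulate a small spatiospectral benchmark
#'
#' FID phantom with three Lorentzian lines per tissue, a smooth
#' field-inhomogeneity map in the encoding operator, full sampling and
#' additive complex noise: the SNR-enhancement (rather than acceleration)
#' regime of the spectroscopic pathway.
#'
#' @param seed RNG seed
#' @param grid voxel grid
#' @param n_fid FID samples
#' @param bandwidth spectral bandwidth (Hz)
#' @param rank retained subspace order
#' @param noise_pct noise as percent of RMS k-space signal
#' @return list with `kspace`, `basis`, `truth`, `grid`, `model`, `anat`
#'   (anatomical reference image with its own contrast)
#' @export
mrsi_benchmark_data <- function(seed = 1L, grid = c(32L, 32L), n_fid = 64L,
                                bandwidth = 1670, rank = 3L, noise_pct = 20) {
  model <- make_tissue_model(seed = seed, grid = grid, n_structures = 3L)
  fmap <- make_field_map(seed = seed, grid = grid, max_hz = 15)
  sim <- simulate_mrsi_series(model, n_fid = n_fid, bandwidth = bandwidth,
                              fieldmap = fmap)
  coils <- make_coil_maps(seed = seed, grid = grid, n_coils = 2L)
  mask <- make_mask(seed = seed, AF = 1, n_center_nav = 4L,
                    n_center_first_frame = 4L, Nt = n_fid, ny = grid[2L])
  y0 <- simulate_kspace(sim$series, coils, mask, noise_sigma = 0)
  m_sampled <- length(y0$samples)
  sigma <- noise_pct / 100 * sqrt(sum(Mod(y0$samples)^2) / m_sampled)
  ks <- simulate_kspace(sim$series, coils, mask, noise_sigma = sigma, seed = seed)
  rank <- min(rank, sim$basis$rank)
  basis <- new_temporal_basis(sim$basis$V[seq_len(rank), , drop = FALSE], "truth-SVD")
  # anatomical reference: label-wise contrast distinct from the FID amplitudes
  set.seed(seed + 9001L)
  anat_vals <- c(0, stats::runif(model$n_labels - 1L, 0.3, 1))
  anat <- matrix(anat_vals[model$label_map + 1L], grid[1L], grid[2L])
  list(kspace = ks, basis = basis, truth = sim$series$data, grid = grid,
       model = model, anat = anat, noise_sigma = sigma)
}
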