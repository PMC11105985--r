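# dense oracle: materialize the Hermitian normal operator by applying it to
# canonical unit vectors and solve the stacked system directly
dense_solve <- function(applyM, b) {
  N <- length(b)
  M <- matrix(0 + 0i, N, N)
  for (j in seq_len(N)) {
    e <- numeric(N)
    e[j] <- 1
    M[, j] <- as.vector(applyM(matrix(e, nrow(b), ncol(b))))
  }
  matrix(solve(M, as.vector(b)), nrow(b), ncol(b))
}

fx_tiny_prob <- function(seed = 50L, grid = c(8L, 8L), Nt = 3L, R = 2L, Nc = 2L, AF = 2) {
  set.seed(seed)
  N <- prod(grid)
  coils <- make_coil_maps(seed, grid, Nc)
  mask <- make_mask(seed, AF = AF, n_center_nav = 2L, n_center_first_frame = 4L,
                    Nt = Nt, ny = grid[2L])
  em <- encoding_model(coils, mask, grid = grid)
  V <- basis_from_series(rand_cplx(N, Nt), R)$V
  C <- rand_cplx(N, R) %*% V
  series <- structure(list(data = C, grid = grid, frame_axis = "echo"),
                      class = "image_series")
  ks <- simulate_kspace(series, coils, mask, noise_sigma = 0)
  list(grid = grid, em = em, V = V, basis = subgenrecon:::new_temporal_basis(V),
       ks = ks, truth = C, N = N, R = R, Nt = Nt)
}

test_that("the anchored parameter-mapping subproblem matches a dense solve", {
  p <- fx_tiny_prob()
  set.seed(51)
  anchors <- rand_cplx(p$N, p$Nt)
  lambda1 <- c(0.1, 0.05, 0.2)
  Vh <- Conj(t(p$V))
  b <- enc_adjoint(p$em, p$ks$samples, p$V) + anchors %*% (lambda1 * Vh)
  applyM <- function(U) enc_normal(p$em, U, p$V) + U %*% (p$V %*% (lambda1 * Vh))
  Uo <- dense_solve(applyM, b)
  U <- subproblem2_t2(p$ks, p$basis, anchors, lambda1, lambda2 = 0)
  expect_lt(relative_l2(U, Uo), 1e-4)   # (relative_l2 is in percent)
  expect_error(subproblem2_t2(p$ks, p$basis, anchors, lambda1[1:2]), "frame")
})

test_that("anchor dominance and term removal behave as limits", {
  p <- fx_tiny_prob()
  set.seed(52)
  anchors_U <- rand_cplx(p$N, p$R)
  anchors <- anchors_U %*% p$V     # anchors inside the subspace for exact dominance
  U <- subproblem2_t2(p$ks, p$basis, anchors, lambda1 = 1e6, lambda2 = 0)
  gap <- relative_l2(U %*% p$V, anchors)
  expect_lt(gap / 100, 1e-3)
  # lambda1 = lambda2 = 0 reduces to the plain subspace least squares
  U0 <- subproblem2_t2(p$ks, p$basis, anchors * 0, lambda1 = 0, lambda2 = 0)
  Ub <- baseline_subspace(p$ks, p$basis, lambda2 = 0)
  expect_lt(relative_l2(U0, Ub), 1e-4)
})

test_that("the spectroscopic subproblem matches a dense Tikhonov solve", {
  p <- fx_tiny_prob(seed = 53L)
  set.seed(54)
  anchors <- rand_cplx(p$N, p$R)
  lambda1 <- c(1.6, 0.8)
  lambda2 <- 0.3
  ew <- array(1, c(p$grid, 2L))    # unit edge weights: plain Tikhonov on gradients
  b <- enc_adjoint(p$em, p$ks$samples, p$V) + sweep(anchors, 2L, lambda1, "*")
  applyM <- function(U) {
    enc_normal(p$em, U, p$V) + sweep(U, 2L, lambda1, "*") +
      lambda2 * subgenrecon:::fd_normal_cols(U, p$grid, ew^2)
  }
  Uo <- dense_solve(applyM, b)
  U <- subproblem2_mrsi(p$ks, p$basis, anchors, lambda1, lambda2, edge_weights = ew)
  expect_lt(relative_l2(U, Uo), 1e-4)
  # anchor dominance
  Ud <- subproblem2_mrsi(p$ks, p$basis, anchors, lambda1 = 1e6, lambda2 = 0)
  expect_lt(relative_l2(Ud, anchors) / 100, 1e-3)
  expect_error(subproblem2_mrsi(p$ks, p$basis, anchors[, 1L, drop = FALSE], 1),
               "rank")
})

test_that("noiseless fully sampled exact-rank data are recovered exactly", {
  m <- make_tissue_model(seed = 55L, grid = c(32L, 32L), n_structures = 3L)
  s <- simulate_t2_series(m, 8.8 * (1:8))
  coils <- make_coil_maps(55L, c(32L, 32L), 3L)
  mask <- make_mask(55L, AF = 1, n_center_nav = 4L, n_center_first_frame = 4L,
                    Nt = 8L, ny = 32L)
  ks <- simulate_kspace(s, coils, mask, noise_sigma = 0)
  V <- basis_from_series(s, 3L)$V
  U <- baseline_subspace(ks, subgenrecon:::new_temporal_basis(V), lambda2 = 0)
  expect_lt(relative_l2(U %*% V, s$data) / 100, 1e-6)
})

test_that("IRLS passes do not increase the joint-sparsity objective", {
  p <- fx_tiny_prob(seed = 56L, grid = c(16L, 16L), Nt = 4L, R = 2L)
  ksn <- p$ks
  set.seed(57)
  # perturb data so the solution is not exact and IRLS has work to do
  ksn$samples <- ksn$samples + 0.01 * array(rand_cplx(length(ksn$samples)),
                                            dim(ksn$samples)) *
    (Mod(ksn$samples) > 0)
  U <- baseline_subspace(ksn, p$basis, lambda2 = 1e-3, n_irls = 6L)
  objs <- attr(U, "objective")
  expect_true(all(diff(objs) <= 1e-6 * objs[1L]))
})

test_that("phase maps from a baseline reconstruction are unit modulus and accurate", {
  m <- make_tissue_model(seed = 58L, grid = c(32L, 32L), n_structures = 2L)
  s <- simulate_t2_series(m, 8.8 * (1:6))
  coils <- make_coil_maps(58L, c(32L, 32L), 3L)
  mask <- make_mask(58L, AF = 1, n_center_nav = 4L, n_center_first_frame = 4L,
                    Nt = 6L, ny = 32L)
  ks <- simulate_kspace(s, coils, mask, noise_sigma = 0)
  V <- basis_from_series(s, 2L)$V
  U <- baseline_subspace(ks, subgenrecon:::new_temporal_basis(V), lambda2 = 0)
  Phi <- sos_phase_source(U %*% V)
  expect_equal(range(Mod(Phi)), c(1, 1), tolerance = 1e-9)
  # reproduces the simulated smooth phase inside the object at full sampling
  inside <- as.vector(m$label_map) >= 1L
  dphi <- Arg(Phi[inside, 3L] * Conj(sos_phase_source(s$data)[inside, 3L]))
  expect_lt(sqrt(mean(dphi^2)), 1e-2)
  # real-valued input gives identically unit phase
  expect_true(all(sos_phase_source(matrix(3.2, 10L, 2L)) == 1 + 0i))
})

test_that("configuration presets reproduce the published weight patterns", {
  l1 <- subgenrecon:::lambda1_weights("gan-only", 16L)
  expect_equal(l1, c(rep(0.1, 10L), rep(0.2, 6L)))
  expect_equal(subgenrecon:::lambda1_weights("proposed", 16L), rep(0.04, 16L))
  expect_error(recon_config(rank = 2L, iters = 0L), "iters")
  expect_error(recon_config(rank = 2L, lambda2 = -1), "lambda2")
})
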