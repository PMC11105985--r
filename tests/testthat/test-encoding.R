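test_that("forward/adjoint pairs satisfy the inner-product identity", {
  fx <- fx_small_enc()
  set.seed(21)
  V <- basis_from_series(rand_cplx(prod(fx$grid), fx$Nt), 3L)$V
  disc <- replicate(20, {
    U <- rand_cplx(prod(fx$grid), 3L)
    Y <- array(rand_cplx(prod(fx$grid) * fx$Nc * fx$Nt), c(fx$grid, fx$Nc, fx$Nt))
    a <- sum(Conj(enc_forward(fx$em, U, V)) * Y)
    b <- sum(Conj(U) * enc_adjoint(fx$em, Y, V))
    Mod(a - b) / Mod(a)
  })
  expect_lt(max(disc), 1e-8)
})

test_that("the normal operator is PSD with norm at most one", {
  fx <- fx_small_enc()
  set.seed(22)
  V <- basis_from_series(rand_cplx(prod(fx$grid), fx$Nt), 2L)$V
  for (i in 1:5) {
    U <- rand_cplx(prod(fx$grid), 2L)
    expect_gte(Re(sum(Conj(U) * enc_normal(fx$em, U, V))), -1e-10)
  }
  # power iteration for the spectral norm
  U <- rand_cplx(prod(fx$grid), 2L)
  nrm <- NA
  for (i in 1:40) {
    U <- enc_normal(fx$em, U, V)
    nrm <- sqrt(sum(Mod(U)^2))
    U <- U / nrm
  }
  expect_lte(nrm, 1 + 1e-6)
})

test_that("full sampling with a unit coil makes the normal operator the identity", {
  grid <- c(16L, 16L)
  coils <- make_coil_maps(1L, grid, 1L)
  coils$maps[1L, ] <- 1 + 0i
  mask <- make_mask(1L, AF = 1, n_center_nav = 2L, n_center_first_frame = 2L,
                    Nt = 4L, ny = 16L)
  em <- encoding_model(coils, mask, grid = grid)
  set.seed(23)
  V <- basis_from_series(rand_cplx(prod(grid), 4L), 2L)$V
  U <- rand_cplx(prod(grid), 2L)
  expect_equal(enc_normal(em, U, V), U, tolerance = 1e-10)
})

test_that("the forward operator is linear and annihilates zero", {
  fx <- fx_small_enc()
  set.seed(24)
  V <- basis_from_series(rand_cplx(prod(fx$grid), fx$Nt), 2L)$V
  U1 <- rand_cplx(prod(fx$grid), 2L)
  U2 <- rand_cplx(prod(fx$grid), 2L)
  y12 <- enc_forward(fx$em, U1 + U2, V)
  expect_equal(y12, enc_forward(fx$em, U1, V) + enc_forward(fx$em, U2, V),
               tolerance = 1e-12)
  expect_true(all(enc_forward(fx$em, U1 * 0, V) == 0))
  expect_error(enc_forward(fx$em, U1[, 1L, drop = FALSE], V), "mismatch")
})

test_that("a unit-modulus field phase leaves the encoding spectrum unchanged", {
  grid <- c(8L, 8L)
  coils <- make_coil_maps(2L, grid, 2L)
  mask <- make_mask(2L, AF = 2, n_center_nav = 2L, n_center_first_frame = 2L,
                    Nt = 2L, ny = 8L)
  fmap <- make_field_map(2L, grid, max_hz = 30)
  em0 <- encoding_model(coils, mask, grid = grid)
  emB <- encoding_model(coils, mask, fieldmap = fmap, grid = grid, dwell_s = 1e-3)
  V <- diag(2L) + 0i
  N <- prod(grid)
  dense_sv <- function(em) {
    M <- matrix(0 + 0i, N * 2L * em$Nc * em$Nt, N * 2L)
    for (j in seq_len(N * 2L)) {
      e <- numeric(N * 2L); e[j] <- 1
      M[, j] <- as.vector(enc_forward(em, matrix(e, N, 2L), V))
    }
    svd(M)$d
  }
  expect_equal(dense_sv(em0), dense_sv(emB), tolerance = 1e-6)
})

test_that("finite differences and the joint-sparsity norm behave as defined", {
  expect_equal(joint_sparsity_norm(finite_difference(matrix(3.7, 8L, 8L))), 0)
  set.seed(26)
  x <- matrix(rnorm(64), 8L, 8L)
  g <- finite_difference(x)
  # single frame: anisotropic TV, matches the direct sum
  direct <- sum(abs(x - x[c(8L, 1:7), ])) + sum(abs(x - x[, c(8L, 1:7)]))
  expect_equal(joint_sparsity_norm(g), direct, tolerance = 1e-12)
  expect_equal(joint_sparsity_norm(finite_difference(-2.5 * x)),
               2.5 * joint_sparsity_norm(g), tolerance = 1e-12)
  # multi-frame: zero iff all frames spatially constant
  C <- matrix(rep(c(1 + 2i, 3 - 1i), each = 64L), 64L, 2L)
  expect_equal(joint_sparsity_norm(finite_difference(C, grid = c(8L, 8L))), 0)
  # adjoint identity for the difference operator
  gg <- array(rnorm(128), c(8L, 8L, 2L))
  expect_equal(sum(finite_difference(x) * gg),
               sum(x * subgenrecon:::fd_adjoint(gg)), tolerance = 1e-12)
})

test_that("edge weights are bounded, flat on constants, small across edges", {
  expect_equal(edge_weights_from_reference(matrix(2, 16L, 16L)),
               array(1, c(16L, 16L, 2L)))
  step <- matrix(0, 16L, 16L)
  step[, 9:16] <- 1
  w <- edge_weights_from_reference(step, sigma = 0.2)
  expect_true(all(w >= 0 & w <= 1))
  expect_lt(w[1L, 9L, 2L], 0.05)          # across the step edge
  expect_equal(w[5L, 5L, 1L], 1)          # flat region
  set.seed(27)
  wr <- edge_weights_from_reference(matrix(rnorm(256), 16L, 16L))
  expect_true(all(wr >= 0 & wr <= 1))
})
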