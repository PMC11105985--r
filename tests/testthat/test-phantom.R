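test_that("tissue models are deterministic with the requested label set", {
  m <- make_tissue_model(seed = 0L, grid = c(64L, 64L), n_structures = 4L)
  expect_setequal(sort(unique(as.vector(m$label_map))), 0:4)
  m2 <- make_tissue_model(seed = 0L, grid = c(64L, 64L), n_structures = 4L)
  expect_identical(m$label_map, m2$label_map)
  m3 <- make_tissue_model(seed = 1L, grid = c(64L, 64L), n_structures = 4L)
  expect_gt(sum(m$label_map != m3$label_map), 0L)
  expect_true(all(m$t2_ms[-1L] > 0))
  expect_true(all(m$pd >= 0))
  expect_error(make_tissue_model(0L, c(16L, 16L), 4L), "grid too small")
})

test_that("multi-echo decay follows the closed form and the exact rank rule", {
  m <- make_tissue_model(seed = 2L, grid = c(32L, 32L), n_structures = 1L)
  # one tissue, TE = T2: magnitude is PD * exp(-1)
  t2 <- m$t2_ms[2L]
  s <- simulate_t2_series(m, t2)
  inside <- as.vector(m$label_map) == 1L
  expect_equal(Mod(s$data[inside, 1L]), rep(m$pd[2L] * exp(-1), sum(inside)),
               tolerance = 1e-12)
  # three distinct T2 values: numerical Casorati rank 3
  m3 <- make_tissue_model(seed = 3L, grid = c(32L, 32L), n_structures = 3L)
  s3 <- simulate_t2_series(m3, 8.8 * (1:16))
  sv <- svd(casorati(s3))$d
  expect_gt(sv[3L] / sv[4L], 1e8)
  expect_lt(sv[4L] / sv[1L], 1e-10)
  expect_error(simulate_t2_series(m3, numeric(0)), "empty")
  expect_error(simulate_t2_series(m3, c(10, -1)), "positive")
})

test_that("spectroscopic phantoms are low rank with a spanning truth basis", {
  m <- make_tissue_model(seed = 4L, grid = c(32L, 32L), n_structures = 3L)
  fmap <- make_field_map(seed = 4L, grid = c(32L, 32L))
  sim <- simulate_mrsi_series(m, n_fid = 150L, bandwidth = 1670, fieldmap = fmap)
  C <- casorati(sim$series)
  sv <- svd(C)$d
  K <- length(m$spec_freq_hz)
  expect_lte(sum(sv > 1e-8 * sv[1L]), K * m$n_labels)
  # basis spans the noiseless temporal space
  V <- sim$basis$V
  resid <- C - (C %*% Conj(t(V))) %*% V
  expect_lt(sqrt(sum(Mod(resid)^2) / sum(Mod(C)^2)), 1e-8)
  # same-label voxels share their FID (field phase lives in the operator)
  lab <- as.vector(m$label_map)
  idx <- which(lab == 1L)[1:2]
  expect_equal(C[idx[1L], ], C[idx[2L], ], tolerance = 1e-12)
  expect_error(simulate_mrsi_series(m, n_fid = 150L, bandwidth = -1), "bandwidth")
  expect_error(simulate_mrsi_series(m, n_fid = 3L, bandwidth = 1670), "n_fid")
})

test_that("field map phase entries have unit modulus", {
  fmap <- make_field_map(seed = 1L, grid = c(32L, 32L), max_hz = 25)
  coils <- make_coil_maps(1L, c(32L, 32L), 2L)
  mask <- make_mask(1L, AF = 1, n_center_nav = 4L, n_center_first_frame = 4L,
                    Nt = 6L, ny = 32L)
  em <- encoding_model(coils, mask, fieldmap = fmap, grid = c(32L, 32L), dwell_s = 6e-4)
  expect_equal(range(Mod(em$B)), c(1, 1), tolerance = 1e-12)
})

test_that("sampling masks honor navigator, first-frame center and AF accounting", {
  ny <- 64L; Nt <- 10L; AF <- 4
  mk <- make_mask(seed = 3L, AF = AF, n_center_nav = 6L, n_center_first_frame = 16L,
                  Nt = Nt, ny = ny)
  expect_true(all(mk$mask[, mk$nav_lines]))
  expect_true(all(mk$mask[1L, mk$first_center]))
  counts <- rowSums(mk$mask)
  expect_true(all(abs(counts[-1L] - ny / AF) <= 1))
  # per-frame sampled fraction within the accounting band
  frac <- counts[-1L] / ny
  expect_true(all(frac >= 1 / AF - 2 / ny & frac <= 1 / AF + 2 / ny))
  expect_error(make_mask(0L, AF = 0.5), "AF")
  expect_error(make_mask(0L, AF = 2, n_center_nav = 1L), "n_center_nav")
})

test_that("coil maps are smooth, nonzero, and unit root-sum-of-squares", {
  cm <- make_coil_maps(seed = 0L, grid = c(32L, 32L), n_coils = 4L)
  expect_true(all(is.finite(Mod(cm$maps))))
  expect_true(all(rowSums(Mod(cm$maps)) > 0))
  rss <- sqrt(colSums(Mod(cm$maps)^2))
  expect_equal(rss, rep(1, ncol(cm$maps)), tolerance = 1e-12)
})

test_that("k-space simulation matches the forward operator and is reproducible", {
  m <- make_tissue_model(seed = 5L, grid = c(32L, 32L), n_structures = 2L)
  s <- simulate_t2_series(m, c(10, 40, 90))
  coils <- make_coil_maps(5L, c(32L, 32L), 3L)
  mask <- make_mask(5L, AF = 2, n_center_nav = 4L, n_center_first_frame = 8L,
                    Nt = 3L, ny = 32L)
  ks0 <- simulate_kspace(s, coils, mask, noise_sigma = 0)
  em <- encoding_model(coils, mask, grid = c(32L, 32L))
  expect_equal(ks0$samples, subgenrecon:::enc_forward_series(em, s$data), tolerance = 1e-12)
  # zeros exactly where the mask is zero
  for (t in 1:3) expect_true(all(ks0$samples[, !mask$mask[t, ], , t] == 0))
  ks1 <- simulate_kspace(s, coils, mask, noise_sigma = 0.01, seed = 9L)
  ks2 <- simulate_kspace(s, coils, mask, noise_sigma = 0.01, seed = 9L)
  expect_identical(ks1$samples, ks2$samples)
  expect_gt(max(Mod(ks1$samples - ks0$samples)), 0)
  badcoils <- make_coil_maps(5L, c(16L, 16L), 3L)
  expect_error(simulate_kspace(s, badcoils, mask), "mismatch")
})

test_that("adjoint-then-forward is identity at full sampling with a single unit coil", {
  grid <- c(16L, 16L)
  coils <- make_coil_maps(1L, grid, 1L)
  coils$maps[1L, ] <- 1 + 0i
  mask <- make_mask(1L, AF = 1, n_center_nav = 2L, n_center_first_frame = 2L,
                    Nt = 2L, ny = 16L)
  set.seed(11)
  C <- rand_cplx(prod(grid), 2L)
  em <- encoding_model(coils, mask, grid = grid)
  y <- subgenrecon:::enc_forward_series(em, C)
  C2 <- subgenrecon:::enc_adjoint_series(em, y)
  expect_equal(C2, C, tolerance = 1e-10)
})

test_that("sum-of-squares reference matches its formula", {
  set.seed(12)
  C <- rand_cplx(64L, 4L)
  r <- sos_reference(C)
  expect_equal(r, sqrt(rowSums(Mod(C)^2)), tolerance = 1e-14)
  expect_true(all(r >= 0))
  expect_equal(sos_reference(C[, 1L, drop = FALSE]), Mod(C[, 1L]), tolerance = 1e-14)
  expect_equal(sos_reference(cbind(C[, 1L], C[, 1L])), sqrt(2) * Mod(C[, 1L]),
               tolerance = 1e-14)
})
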