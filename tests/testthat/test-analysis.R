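test_that("relative l2 error matches its definition", {
  set.seed(61)
  x <- rand_cplx(100L)
  expect_equal(relative_l2(x, x), 0)
  expect_equal(relative_l2(1.1 * x, x), 10, tolerance = 1e-10)
  y <- rand_cplx(100L)
  expect_equal(relative_l2(y, x),
               100 * sqrt(sum(Mod(y - x)^2)) / sqrt(sum(Mod(x)^2)),
               tolerance = 1e-12)
  msk <- rep(c(TRUE, FALSE), 50L)
  expect_equal(relative_l2(y, x, msk),
               100 * sqrt(sum(Mod((y - x)[msk])^2)) / sqrt(sum(Mod(x[msk])^2)),
               tolerance = 1e-12)
  expect_error(relative_l2(x, x * 0), "zero")
  expect_error(relative_l2(x[1:10], x), "match")
})

test_that("T2 fitting is exact on noiseless data", {
  te <- c(20, 60)
  pd <- 1.4; t2 <- 80
  S <- matrix(pd * exp(-te / t2), 1L, 2L, byrow = TRUE)
  fit <- fit_t2(S, te)
  expect_equal(fit$t2_ms[1L], 80, tolerance = 1e-4)
  expect_equal(fit$pd[1L], 1.4, tolerance = 1e-6)
  # log-linear initialization already solves the noiseless problem
  te16 <- 8.8 * (1:16)
  S16 <- matrix(rep(0.9 * exp(-te16 / 55), each = 5L), 5L, 16L)
  f <- fit_t2(S16, te16, max_iter = 0L)
  expect_equal(unname(f$t2_ms), rep(55, 5L), tolerance = 1e-8)
  # all-zero voxels are excluded
  S16[3L, ] <- 0
  f2 <- fit_t2(S16, te16)
  expect_true(is.nan(f2$t2_ms[3L]))
  expect_error(fit_t2(S16[, 1L, drop = FALSE], te16[1L]), "two echoes")
})

test_that("T2 estimates are nearly unbiased with small spread at SNR 50", {
  te <- 8.8 * (1:16)
  set.seed(62)
  for (t2_true in c(50, 80, 120)) {
    n <- 350L
    S <- outer(rep(1, n), exp(-te / t2_true))
    S <- abs(S + matrix(rnorm(n * 16L, sd = 1 / 50), n, 16L))
    fit <- fit_t2(S, te)
    err <- (fit$t2_ms - t2_true) / t2_true
    expect_lt(abs(mean(err)), 0.005)
    expect_lt(sqrt(mean(err^2)), 0.03)
    expect_lt(stats::median(abs(err)), 0.02)
  }
})

test_that("spectral window maps integrate amplitudes correctly", {
  # single-label, single-line FID: the map is proportional to the amplitude
  grid <- c(8L, 8L)
  N <- prod(grid)
  bw <- 1000
  Nt <- 64L
  tk <- (0:(Nt - 1L)) / bw
  amp <- seq(0.5, 2, length.out = N)
  C <- outer(amp, exp((2i * pi * 125 - pi * 10) * tk))
  V <- basis_from_series(C, 1L)$V
  U <- project_to_subspace(C, V)
  # bin spacing is bw/Nt = 15.625 Hz; (130.1, 130.2) straddles no bin
  maps <- mrsi_maps(U, V, list(line = c(100, 150), empty = c(130.1, 130.2),
                               far = c(-400, -350)),
                    bandwidth = bw, grid = grid)
  expect_equal(stats::cor(as.vector(maps$line), amp), 1, tolerance = 1e-6)
  expect_true(all(maps$empty == 0))
  expect_lt(max(abs(maps$far)) / max(maps$line), 0.05)  # Lorentzian tail only
  # windows covering the whole band capture the total spectral magnitude
  full <- mrsi_maps(U, V, list(all = c(-bw / 2, bw / 2)), bandwidth = bw, grid = grid)
  spec_total <- rowSums(Mod(t(apply(C, 1L, stats::fft))))
  expect_equal(as.vector(full$all), spec_total, tolerance = 1e-8)
  expect_error(mrsi_maps(U, V, list(bad = c(0, 2 * bw)), bandwidth = bw), "bandwidth")
})

test_that("sweep reports are reproducible and near zero without undersampling", {
  sim <- function(AF, seed) {
    m <- make_tissue_model(seed, c(32L, 32L), 2L)
    s <- simulate_t2_series(m, 8.8 * (1:6))
    coils <- make_coil_maps(seed, c(32L, 32L), 2L)
    mask <- make_mask(seed, AF = AF, n_center_nav = 4L, n_center_first_frame = 6L,
                      Nt = 6L, ny = 32L)
    ks <- simulate_kspace(s, coils, mask, noise_sigma = 0)
    list(kspace = ks, basis = basis_from_series(s, 2L), truth = s$data,
         te_ms = 8.8 * (1:6), grid = c(32L, 32L))
  }
  methods <- list(subspace = function(ks, b, truth) baseline_subspace(ks, b, 0) %*% b$V)
  rep1 <- sweep_report(methods, AFs = 1, seeds = c(1L, 2L), sim = sim)
  expect_true(all(rep1$img_err_pct < 1e-5))
  rep2 <- sweep_report(methods, AFs = 1, seeds = c(1L, 2L), sim = sim)
  expect_equal(rep1, rep2)
  # serialization round-trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rep1, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$img_err_pct, rep1$img_err_pct, tolerance = 1e-12)
  expect_error(sweep_report(list(), 1, 1, sim), "method")
})
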