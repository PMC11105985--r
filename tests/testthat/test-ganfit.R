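test_that("l1-ball projection is exact against the soft-threshold construction", {
  expect_equal(project_l1_ball(c(2, 1), c(0, 0), 1), c(1, 0))
  w <- c(0.2, -0.1, 0.05)
  expect_identical(project_l1_ball(w, rep(0, 3), 1), w)   # interior point
  expect_equal(project_l1_ball(w, c(5, 5, 5), 0), c(5, 5, 5))
  expect_error(project_l1_ball(w, w, -1), "radius")
  # brute-force oracle: dense threshold search over the active set
  oracle <- function(w, center, r) {
    d <- w - center
    if (sum(abs(d)) <= r) return(w)
    taus <- sort(c(0, abs(d)))
    f <- function(tau) sum(pmax(abs(d) - tau, 0)) - r
    lo <- max(taus[vapply(taus, f, 1) >= 0])
    hi <- min(taus[vapply(taus, f, 1) <= 0])
    tau <- if (hi > lo) {
      k <- sum(abs(d) > lo)
      (sum(abs(d)[abs(d) > lo]) - r) / k
    } else lo
    center + sign(d) * pmax(abs(d) - tau, 0)
  }
  set.seed(41)
  for (i in 1:100) {
    w <- rnorm(10L); c0 <- rnorm(10L); r <- runif(1, 0.1, 4)
    p <- project_l1_ball(w, c0, r)
    expect_equal(p, oracle(w, c0, r), tolerance = 1e-8)
    expect_lte(sum(abs(p - c0)), r + 1e-9)
    expect_equal(project_l1_ball(p, c0, r), p, tolerance = 1e-12)
  }
})

test_that("zero-step inversion returns the initialization unchanged", {
  gen <- fx_tiny_gen()
  init <- mean_latent(gen, n_draws = 100L, seed = 1L)
  tgt <- synthesize(gen, random_latents(gen, 1L, seed = 2L))
  cfg <- inversion_config(steps_tail = 0L, steps_proj = 0L, steps_joint = 0L)
  res <- ilo_invert(gen, tgt, cfg, init = init)
  expect_identical(res$latents, init)
})

test_that("staged inversion recovers self-generated targets and tracks stage losses", {
  gen <- fx_tiny_gen()
  wstar <- random_latents(gen, 1L, seed = 7L)
  tgt <- synthesize(gen, wstar)
  cfg <- inversion_config(steps_tail = 80L, steps_proj = 60L, steps_joint = 60L)
  res <- ilo_invert(gen, tgt, cfg)
  fit <- synthesize(gen, res$latents)
  expect_lt(100 * sqrt(sum((fit - tgt)^2) / sum(tgt^2)), 2)
  # stage losses never rise above the initialization
  expect_true(all(res$stage_loss <= res$stage_loss[1L] + 1e-9))
  expect_lte(res$loss, min(res$stage_loss) + 1e-9)
  expect_error(ilo_invert(gen, matrix(NaN, 16L, 16L), cfg), "finite")
})

test_that("frozen latent levels are bit-identical before and after inversion", {
  gen <- fx_tiny_gen()
  init <- mean_latent(gen, n_draws = 100L, seed = 3L)
  tgt <- synthesize(gen, random_latents(gen, 1L, seed = 4L))
  L <- gen$spec$levels
  cfg <- inversion_config(steps_tail = 20L, steps_proj = 10L, steps_joint = 20L,
                          frozen_levels = L)
  res <- ilo_invert(gen, tgt, cfg, init = init)
  expect_identical(res$latents[[L]], init[[L]])
  expect_false(identical(res$latents[[1L]], init[[1L]]))
  expect_error(ilo_invert(gen, tgt, inversion_config(frozen_levels = 99L), init = init),
               "frozen")
})

test_that("chained-ball series inversion collapses and relaxes at the radius limits", {
  gen <- fx_tiny_gen()
  f1 <- synthesize(gen, random_latents(gen, 1L, seed = 8L))
  f2 <- synthesize(gen, random_latents(gen, 1L, seed = 9L))
  targets <- array(c(f1, f2, f2), c(16L, 16L, 3L))
  cfg0 <- inversion_config(steps_tail = 30L, steps_proj = 20L, steps_joint = 30L,
                           radius = 0)
  res0 <- invert_series(gen, targets, cfg0)
  expect_equal(res0$latents[[2L]], res0$latents[[1L]], tolerance = 0)
  expect_equal(res0$latents[[3L]], res0$latents[[1L]], tolerance = 0)
  # infinite radius equals independent warm-started inversions
  cfgI <- inversion_config(steps_tail = 30L, steps_proj = 20L, steps_joint = 30L,
                           radius = Inf)
  resI <- invert_series(gen, targets, cfgI)
  expect_false(identical(resI$latents[[2L]], resI$latents[[1L]]))
  expect_error(invert_series(gen, targets,
                             inversion_config(radius = c(1, 1, 1, 1))),
               "length")
})

test_that("ball-constrained iterates stay feasible", {
  gen <- fx_tiny_gen()
  f1 <- synthesize(gen, random_latents(gen, 1L, seed = 10L))
  f2 <- synthesize(gen, random_latents(gen, 1L, seed = 11L))
  targets <- array(c(f1, f2), c(16L, 16L, 2L))
  r <- 0.5
  cfg <- inversion_config(steps_tail = 20L, steps_proj = 10L, steps_joint = 30L,
                          radius = r)
  res <- invert_series(gen, targets, cfg)
  gap <- sum(abs(subgenrecon:::lat_flatten(res$latents[[2L]]) -
                   subgenrecon:::lat_flatten(res$latents[[1L]])))
  expect_lte(gap, r + 1e-9)
})

test_that("staged inversion strictly improves on its initialization across targets", {
  gen <- fx_tiny_gen()
  init <- mean_latent(gen, n_draws = 100L, seed = 1L)
  cfg <- inversion_config(start_split = 2L, steps_tail = 40L, steps_proj = 30L,
                          steps_joint = 30L)
  for (i in 1:10) {
    tgt <- synthesize(gen, random_latents(gen, 1L, seed = 100L + i))
    res <- ilo_invert(gen, tgt, cfg, init = init)
    # large reduction from the mean-latent start, and the joint stage never
    # returns anything worse than the best composed stack
    expect_lt(res$loss, 0.5 * res$stage_loss[["initial"]])
    expect_true(all(diff(res$stage_loss) <= 1e-9))
  }
})

test_that("data-consistency latent fitting matches encoded self-generated frames", {
  gen <- fx_tiny_gen()
  grid <- c(16L, 16L)
  wstar <- random_latents(gen, 1L, seed = 12L)
  mag <- synthesize(gen, wstar)
  set.seed(44)
  Phi <- matrix(exp(1i * 0.3 * rnorm(prod(grid))), prod(grid), 1L)
  coils <- make_coil_maps(9L, grid, 2L)
  mask <- make_mask(9L, AF = 1, n_center_nav = 2L, n_center_first_frame = 2L,
                    Nt = 1L, ny = 16L)
  series <- structure(list(data = matrix(Phi * as.vector(mag), prod(grid), 1L),
                           grid = grid, frame_axis = "echo"),
                      class = "image_series")
  ks <- simulate_kspace(series, coils, mask, noise_sigma = 0)
  cfg <- inversion_config(steps_tail = 60L, steps_proj = 40L, steps_joint = 60L)
  res <- latent_init_data_consistency(gen, ks, Phi, cfg, scale = 1)
  fit <- synthesize(gen, res$latents[[1L]])
  expect_lt(100 * sqrt(sum((fit - mag)^2) / sum(mag^2)), 3)
  # determinism
  res2 <- latent_init_data_consistency(gen, ks, Phi, cfg, scale = 1)
  expect_identical(res$latents, res2$latents)
  # degenerate: nothing sampled -> loss 0, initialization returned
  ks0 <- ks
  ks0$mask$mask[] <- FALSE
  ks0$mask$nav_lines <- integer(0)
  res0 <- latent_init_data_consistency(gen, ks0, Phi, cfg, scale = 1)
  expect_equal(res0$loss, 0)
  expect_error(latent_init_data_consistency(gen, ks, NULL, cfg), "phase")
})
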