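# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small encoding setup on a 16x16 grid (random series, no tissue model)
fx_small_enc <- function(seed = 7L, grid = c(16L, 16L), Nt = 5L, Nc = 3L, AF = 2) {
  set.seed(seed)
  N <- prod(grid)
  coils <- make_coil_maps(seed, grid, Nc)
  mask <- make_mask(seed, AF = AF, n_center_nav = 4L, n_center_first_frame = 6L,
                    Nt = Nt, ny = grid[2L])
  em <- encoding_model(coils, mask, grid = grid)
  list(grid = grid, Nt = Nt, Nc = Nc, coils = coils, mask = mask, em = em)
}

rand_cplx <- function(n, m = NULL) {
  if (is.null(m)) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  else matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)), n, m)
}

# tiny generator (16x16, 3 levels) for cheap inversion mechanics tests
fx_tiny_gen <- function() {
  fx_get("tiny_gen", function() {
    generator_init(generator_spec(resolution = 16L, output = "magnitude"), seed = 5L)
  })
}

# the desk-scale pretrained magnitude prior shared by adaptation and
# reconstruction tests (also exercised by the pretraining test itself)
fx_prior <- function() {
  fx_get("prior", function() {
    corpus <- phantom_corpus(300L, 64L, seed = 42L)
    pretrain_generator(generator_spec(resolution = 64L, output = "magnitude"),
                       corpus, steps = 300L, batch = 8L, seed = 42L)
  })
}

# benchmark data caches keyed by seed
fx_bench <- function(seed, AF = 4) {
  fx_get(sprintf("bench_%d_af%g", seed, AF), function() t2_benchmark_data(seed = seed, AF = AF))
}

# subject-adapted generator for a benchmark seed
fx_adapted <- function(seed, AF = 4) {
  fx_get(sprintf("adapted_%d_af%g", seed, AF), function() {
    d <- fx_bench(seed, AF)
    U0 <- baseline_subspace(d$kspace, d$basis, lambda2 = 1e-6)
    sos <- matrix(sos_reference(U0 %*% d$basis$V), d$grid[1L], d$grid[2L])
    adapt_to_reference(fx_prior(), sos)
  })
}

# comparative benchmark: all four methods over five seeds at AF = 4; the
# proposed pathway at seed 1 runs one extra outer iteration so the tail of
# its error trajectory is observable
fx_bench_suite <- function() {
  fx_get("bench_suite", function() {
    shared <- new.env(parent = emptyenv())
    methods <- t2_method_suite(fx_prior(), cache = shared)
    methods6 <- t2_method_suite(fx_prior(), iters = 6L, cache = shared)
    errs <- list()
    hist1 <- NULL
    for (sd in 1:5) {
      d <- fx_bench(sd)
      for (m in names(methods)) {
        if (m == "proposed" && sd == 1L) {
          st <- methods6$proposed(d$kspace, d$basis, d$truth)
          hist1 <- st$history
          err <- st$history$rel_err_pct[5L]   # iteration-5 output, as elsewhere
        } else {
          res <- methods[[m]](d$kspace, d$basis, d$truth)
          series <- if (inherits(res, "recon_state")) res$series else res
          err <- relative_l2(series, d$truth)
        }
        errs[[length(errs) + 1L]] <- data.frame(method = m, seed = sd, err = err,
                                                stringsAsFactors = FALSE)
      }
    }
    list(errors = do.call(rbind, errs), proposed_seed1_history = hist1)
  })
}
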