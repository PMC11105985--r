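#' Relative l2 error in percent
#'
#' `100 * ||x - ref||_2 / ||ref||_2` over (optionally masked) entries; the
#' headline quantitative metric, computed on complex values when given
#' complex input.
#'
#' @param x estimate (any numeric/complex array)
#' @param ref reference of the same shape
#' @param mask optional logical array selecting entries
#' @return error in percent
#' @export
relative_l2 <- function(x, ref, mask = NULL) {
  if (length(x) != length(ref)) stop("shapes must match")
  if (!is.null(mask)) {
    x <- x[mask]; ref <- ref[mask]
  }
  den <- sqrt(sum(Mod(ref)^2))
  if (den == 0) stop("reference has zero norm")
  100 * sqrt(sum(Mod(x - ref)^2)) / den
}

#' Object-region mask from a sum-of-squares reference
#'
#' Thresholds the reference at 10 percent of its 99th percentile.
#'
#' @param ref real reference image
#' @return logical matrix
#' @export
fit_mask <- function(ref) {
  thr <- 0.1 * stats::quantile(ref, 0.99, names = FALSE)
  ref > thr
}

#' Voxelwise mono-exponential T2 fitting
#'
#' Fits `PD * exp(-TE / T2)` per voxel: log-linear regression for the
#' initialization (exact in the noiseless case), then vectorized
#' Gauss-Newton refinement of the nonlinear least-squares problem, with T2
#' bounded to (1, 2000) ms. Voxels outside the mask (or all-zero) get NaN.
#'
#' @param series magnitude array `(nx, ny, Nt)` or `N x Nt` matrix
#' @param te_schedule echo times in ms
#' @param mask logical object mask (default: all voxels with positive signal)
#' @param max_iter Gauss-Newton iterations
#' @return a `t2_map` list: `t2_ms`, `pd`, `mask` (matrices when the grid is
#'   known)
#' @export
fit_t2 <- function(series, te_schedule, mask = NULL, max_iter = 20L) {
  grid <- NULL
  if (is.array(series) && length(dim(series)) == 3L) {
    d <- dim(series)
    grid <- d[1:2]
    series <- matrix(series, d[1L] * d[2L], d[3L])
  }
  Nt <- length(te_schedule)
  if (ncol(series) != Nt) stop("series frame count must match te_schedule")
  if (Nt < 2L) stop("at least two echoes are required")
  S <- Mod(series)
  if (is.null(mask)) mask <- rowSums(S) > 0 else mask <- as.vector(mask)
  mask <- mask & apply(S > 0, 1L, all)
  N <- nrow(S)
  t2 <- rep(NaN, N); pd <- rep(NaN, N)
  idx <- which(mask)
  if (length(idx)) {
    te <- as.numeric(te_schedule)
    Y <- log(S[idx, , drop = FALSE])
    # log-linear init: slope/intercept per voxel
    mt <- mean(te); my <- rowMeans(Y)
    slope <- (Y %*% (te - mt)) / sum((te - mt)^2)
    r2 <- pmin(pmax(-1 / slope, 1.0001), 2000)
    a <- exp(my - slope * mt)
    # Gauss-Newton on (log PD, R2 = 1/T2) in the nonlinear model
    lp <- log(a); rr <- 1 / r2
    for (it in seq_len(max_iter)) {
      E <- exp(lp %*% t(rep(1, Nt)) - rr %*% t(te))   # model values
      Rm <- S[idx, , drop = FALSE] - E
      # Jacobian columns: dE/dlp = E ; dE/drr = -te * E
      J11 <- rowSums(E * E)
      J12 <- -rowSums(E * E * rep(te, each = length(idx)))
      J22 <- rowSums(E * E * rep(te^2, each = length(idx)))
      g1 <- rowSums(Rm * E)
      g2 <- -rowSums(Rm * E * rep(te, each = length(idx)))
      det <- J11 * J22 - J12^2
      det[det <= 0] <- Inf
      d1 <- (J22 * g1 - J12 * g2) / det
      d2 <- (-J12 * g1 + J11 * g2) / det
      lp <- lp + d1
      rr <- pmin(pmax(rr + d2, 1 / 2000), 1 / 1.0001)
      if (max(abs(d1), abs(d2)) < 1e-12) break
    }
    t2[idx] <- 1 / rr
    pd[idx] <- exp(lp)
  }
  if (!is.null(grid)) {
    t2 <- matrix(t2, grid[1L], grid[2L])
    pd <- matrix(pd, grid[1L], grid[2L])
    mask <- matrix(mask, grid[1L], grid[2L])
  }
  structure(list(t2_ms = t2, pd = pd, mask = mask), class = "t2_map")
}

#' Spectral amplitude maps from a subspace reconstruction
#'
#' Forms the spatiospectral function `UV`, Fourier-transforms each voxel FID
#' to a spectrum, and integrates the magnitude spectrum over named frequency
#' windows.
#'
#' @param U complex `N x R` coefficients
#' @param V complex `R x Nt` temporal basis
#' @param peak_windows named list of `c(lo, hi)` frequency windows in Hz
#' @param bandwidth spectral bandwidth in Hz
#' @param grid `(nx, ny)` for map reshaping
#' @return named list of real amplitude maps
#' @export
mrsi_maps <- function(U, V, peak_windows, bandwidth, grid = NULL) {
  C <- U %*% V
  Nt <- ncol(C)
  freqs <- (seq_len(Nt) - 1L) / Nt * bandwidth
  freqs[freqs >= bandwidth / 2] <- freqs[freqs >= bandwidth / 2] - bandwidth
  spec <- t(apply(C, 1L, function(fid) Mod(stats::fft(fid))))
  out <- vector("list", length(peak_windows))
  names(out) <- names(peak_windows)
  for (i in seq_along(peak_windows)) {
    w <- peak_windows[[i]]
    if (w[1L] < -bandwidth / 2 || w[2L] > bandwidth / 2)
      stop("window outside the spectral bandwidth")
    sel <- freqs >= w[1L] & freqs <= w[2L]
    m <- if (any(sel)) rowSums(spec[, sel, drop = FALSE]) else numeric(nrow(spec))
    if (!is.null(grid)) m <- matrix(m, grid[1L], grid[2L])
    out[[i]] <- m
  }
  out
}

#' Method/acceleration sweep error report
#'
#' Runs each reconstruction method at each acceleration factor and seed on
#' freshly simulated phantom data and tabulates image-domain (and, for the
#' parameter-mapping application, T2-map) relative l2 errors.
#'
#' @param methods named list of functions `function(kspace, basis, truth)`
#'   returning a `recon_state` or an `N x Nt` series
#' @param AFs acceleration factors to sweep
#' @param seeds phantom/noise seeds
#' @param sim function `function(AF, seed)` returning a list with `kspace`,
#'   `basis`, `truth` (series matrix), `te_ms`, `grid`
#' @return an `error_report` data frame (method, AF, seed, image and T2
#'   errors)
#' @export
sweep_report <- function(methods, AFs, seeds, sim) {
  if (length(methods) < 1L) stop("at least one method is required")
  rows <- list()
  for (AF in AFs) for (sd in seeds) {
    d <- sim(AF, sd)
    sosr <- matrix(sos_reference(d$truth), d$grid[1L], d$grid[2L])
    msk <- fit_mask(sosr)
    t2_true <- if (!is.null(d$te_ms))
      fit_t2(array(Mod(d$truth), c(d$grid, ncol(d$truth))), d$te_ms, msk) else NULL
    for (m in names(methods)) {
      res <- methods[[m]](d$kspace, d$basis, d$truth)
      series <- if (inherits(res, "recon_state")) res$series else res
      img_err <- relative_l2(series, d$truth)
      t2_err <- NA_real_
      if (!is.null(t2_true)) {
        t2_est <- fit_t2(array(Mod(series), c(d$grid, ncol(series))), d$te_ms, msk)
        sel <- msk & is.finite(t2_true$t2_ms) & is.finite(t2_est$t2_ms)
        t2_err <- relative_l2(t2_est$t2_ms[sel], t2_true$t2_ms[sel])
      }
      rows[[length(rows) + 1L]] <- data.frame(method = m, AF = AF, seed = sd,
                                              img_err_pct = img_err,
                                              t2_err_pct = t2_err)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_report", class(out))
  out
}
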