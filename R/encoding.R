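# Unitary, DC-centered 2D FFT pair. Image and k-space grids are aligned by
# fftshift pairs so operator norms are clean (||F|| = 1).

fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- c((floor(nx / 2) + 1L):nx, 1L:floor(nx / 2))
  sy <- c((floor(ny / 2) + 1L):ny, 1L:floor(ny / 2))
  m[sx, sy, drop = FALSE]
}

ifftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- c((nx - floor(nx / 2) + 1L):nx, 1L:(nx - floor(nx / 2)))
  sy <- c((ny - floor(ny / 2) + 1L):ny, 1L:(ny - floor(ny / 2)))
  m[sx, sy, drop = FALSE]
}

fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

ifft2c <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))

#' SENSE encoding model
#'
#' Bundles the linear pieces of the acquisition: per-coil sensitivity
#' weighting, unitary centered Fourier transform, phase-encode sampling and
#' (for spectroscopic data) the field-inhomogeneity phase
#' `exp(i 2 pi df(x) t_k)` applied before encoding.
#'
#' @param coils a `coil_maps` object
#' @param mask a `sampling_mask` object
#' @param fieldmap optional `field_map`; requires `dwell_s`
#' @param grid `(nx, ny)` voxel grid
#' @param dwell_s FID dwell time in seconds (fieldmap phase evolution)
#' @return an `encoding_model` object
#' @export
encoding_model <- function(coils, mask, fieldmap = NULL, grid = coils$grid,
                           dwell_s = NULL) {
  stopifnot(inherits(coils, "coil_maps"), inherits(mask, "sampling_mask"))
  if (!all(coils$grid == grid)) stop("coil/grid mismatch")
  B <- NULL
  if (!is.null(fieldmap)) {
    if (is.null(dwell_s)) stop("fieldmap phase needs dwell_s")
    tk <- (seq_len(mask$Nt) - 1L) * dwell_s
    B <- exp(outer(2i * pi * as.vector(fieldmap$df_hz), tk))  # N x Nt, unit modulus
  }
  structure(list(coils = coils, mask = mask, B = B, grid = grid,
                 Nc = coils$n_coils, Nt = mask$Nt), class = "encoding_model")
}

# 0/1 sampled-entry indicator per frame on the voxel grid (N x Nt)
sampling_weights <- function(em) {
  nx <- em$grid[1L]; ny <- em$grid[2L]
  w <- matrix(0, nx * ny, em$Nt)
  for (t in seq_len(em$Nt)) {
    m <- matrix(0, nx, ny)
    m[, em$mask$mask[t, ]] <- 1
    w[, t] <- as.vector(m)
  }
  w
}

# forward on a full series (complex N x Nt) -> zero-filled (nx, ny, Nc, Nt)
enc_forward_series <- function(em, C) {
  nx <- em$grid[1L]; ny <- em$grid[2L]
  if (nrow(C) != nx * ny || ncol(C) != em$Nt) stop("series shape mismatch")
  y <- array(0 + 0i, c(nx, ny, em$Nc, em$Nt))
  for (t in seq_len(em$Nt)) {
    img <- C[, t]
    if (!is.null(em$B)) img <- img * em$B[, t]
    keep <- em$mask$mask[t, ]
    for (c in seq_len(em$Nc)) {
      k <- fft2c(matrix(em$coils$maps[c, ] * img, nx, ny))
      k[, !keep] <- 0 + 0i
      y[, , c, t] <- k
    }
  }
  y
}

# adjoint into series space: (nx, ny, Nc, Nt) -> complex N x Nt
enc_adjoint_series <- function(em, y) {
  nx <- em$grid[1L]; ny <- em$grid[2L]
  C <- matrix(0 + 0i, nx * ny, em$Nt)
  for (t in seq_len(em$Nt)) {
    keep <- em$mask$mask[t, ]
    accv <- rep(0 + 0i, nx * ny)
    for (c in seq_len(em$Nc)) {
      k <- y[, , c, t]
      k[, !keep] <- 0 + 0i
      accv <- accv + Conj(em$coils$maps[c, ]) * as.vector(ifft2c(k))
    }
    if (!is.null(em$B)) accv <- accv * Conj(em$B[, t])
    C[, t] <- accv
  }
  C
}

#' Forward, adjoint and normal operators on spatial coefficients
#'
#' `enc_forward` maps spatial coefficients `U` (complex `N x R`) through the
#' subspace expansion `UV` and the SENSE encoding to zero-filled k-space;
#' `enc_adjoint` is its exact adjoint; `enc_normal` composes the two
#' (Hermitian positive semidefinite).
#'
#' @param em an [encoding_model()]
#' @param U complex `N x R` spatial coefficient matrix
#' @param V complex `R x Nt` temporal basis (orthonormal rows)
#' @param y zero-filled k-space array `(nx, ny, Nc, Nt)`
#' @return `enc_forward`: k-space array; `enc_adjoint`/`enc_normal`: `N x R`
#' @export
enc_forward <- function(em, U, V) {
  if (ncol(U) != nrow(V)) stop("U/V rank mismatch")
  enc_forward_series(em, U %*% V)
}

#' @rdname enc_forward
#' @export
enc_adjoint <- function(em, y, V) {
  enc_adjoint_series(em, y) %*% Conj(t(V))
}

#' @rdname enc_forward
#' @export
enc_normal <- function(em, U, V) {
  enc_adjoint(em, enc_forward(em, U, V), V)
}

## ---- finite differences and sparsity ----------------------------------------

#' Periodic finite differences
#'
#' First-order forward differences along both image axes with periodic
#' boundary (consistent with the FFT grid). Accepts a matrix (single frame)
#' or an `N x Nt` series with `grid`.
#'
#' @param x image matrix, or `N x Nt` matrix with `grid` supplied
#' @param grid `(nx, ny)` when `x` is in Casorati layout
#' @return array `(nx, ny, 2)` or `(nx, ny, 2, Nt)` of gradients
#' @export
finite_difference <- function(x, grid = NULL) {
  if (is.matrix(x) && is.null(grid)) {
    nx <- nrow(x); ny <- ncol(x)
    g <- array(if (is.complex(x)) 0 + 0i else 0, c(nx, ny, 2L))
    g[, , 1L] <- x - x[c(nx, seq_len(nx - 1L)), , drop = FALSE]
    g[, , 2L] <- x - x[, c(ny, seq_len(ny - 1L)), drop = FALSE]
    return(g)
  }
  nx <- grid[1L]; ny <- grid[2L]
  Nt <- ncol(x)
  g <- array(if (is.complex(x)) 0 + 0i else 0, c(nx, ny, 2L, Nt))
  for (t in seq_len(Nt)) g[, , , t] <- finite_difference(matrix(x[, t], nx, ny))
  g
}

# adjoint of finite_difference for a single frame: (nx, ny, 2) -> matrix
fd_adjoint <- function(g) {
  gx <- g[, , 1L]; gy <- g[, , 2L]
  nx <- nrow(gx); ny <- ncol(gx)
  (gx - gx[c(seq_len(nx - 1L) + 1L, 1L), , drop = FALSE]) +
    (gy - gy[, c(seq_len(ny - 1L) + 1L, 1L), drop = FALSE])
}

#' Joint-sparsity (l2,1) norm of gradient stacks
#'
#' Sums, over voxels and gradient directions, the l2 norm across frames:
#' zero iff every frame is spatially constant.
#'
#' @param g gradient array `(nx, ny, 2, Nt)` (or `(nx, ny, 2)`)
#' @return a nonnegative scalar
#' @export
joint_sparsity_norm <- function(g) {
  d <- dim(g)
  if (length(d) == 3L) return(sum(Mod(g)))
  m <- matrix(Mod(g)^2, prod(d[1:3]), d[4L])
  sum(sqrt(rowSums(m)))
}

#' Edge weights from a reference image
#'
#' `w_d(x) = exp(-|grad_d ref|^2 / sigma^2)` of the magnitude-normalized
#' reference: close to 1 in flat regions, near 0 across strong edges. Used by
#' the edge-weighted quadratic regularizer of the spectroscopic pathway.
#'
#' @param reference real or complex reference image (matrix)
#' @param sigma edge scale; default is twice the median absolute gradient
#' @return array `(nx, ny, 2)` of weights in `[0, 1]`
#' @export
edge_weights_from_reference <- function(reference, sigma = NULL) {
  r <- Mod(reference)
  if (!all(is.finite(r))) stop("reference must be finite")
  mx <- max(r)
  if (mx > 0) r <- r / mx
  g <- finite_difference(r)
  ga <- abs(g)
  if (max(ga) == 0) return(array(1, dim(g)))
  if (is.null(sigma)) {
    # scale set by the typical (background) gradient so genuine edges get
    # weights near zero; piecewise-constant references have median 0 and
    # fall back to a fraction of the edge height
    sigma <- 2 * stats::median(ga)
    if (!is.finite(sigma) || sigma == 0) sigma <- 0.2 * max(ga)
  }
  exp(-(ga / sigma)^2)
}
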