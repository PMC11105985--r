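new_temporal_basis <- function(V, provenance = "supplied") {
  structure(list(V = V, rank = nrow(V), provenance = provenance),
            class = "temporal_basis")
}

#' Casorati matrix of an image series
#'
#' Cascades the spatial dimensions along rows and the temporal/parametric
#' dimension along columns; `uncasorati()` reverses the frame reshaping.
#'
#' @param series an `image_series`, a complex `N x Nt` matrix, or a 3D array
#'   `(nx, ny, Nt)`
#' @return complex `N x Nt` matrix
#' @export
casorati <- function(series) {
  if (inherits(series, "image_series")) return(series$data)
  if (is.array(series) && length(dim(series)) == 3L) {
    d <- dim(series)
    return(matrix(series, d[1L] * d[2L], d[3L]))
  }
  as.matrix(series)
}

#' @rdname casorati
#' @param C Casorati matrix
#' @param grid `(nx, ny)`
#' @export
uncasorati <- function(C, grid) {
  array(C, c(grid[1L], grid[2L], ncol(C)))
}

#' Estimate the temporal basis from navigator k-space
#'
#' Reconstructs a low-resolution time series from the navigator (center)
#' phase-encode lines — Hamming apodization over the center block, zero-fill,
#' per-frame unitary inverse FFT, conjugate-sensitivity coil combination —
#' and takes the top right singular vectors of its Casorati matrix.
#'
#' @param kspace a `kspace` object whose mask contains navigator lines
#' @param rank subspace order, `1 <= rank <= Nt`
#' @return a `temporal_basis` with orthonormal rows and the normalized
#'   singular values attached (`sv` element) for rank inspection
#' @export
estimate_basis <- function(kspace, rank) {
  stopifnot(inherits(kspace, "kspace"))
  Nt <- kspace$mask$Nt
  if (rank < 1L || rank > Nt) stop("rank must be between 1 and the number of frames")
  nav <- kspace$mask$nav_lines
  sampled_all <- apply(kspace$mask$mask[, nav, drop = FALSE], 2L, all)
  if (!all(sampled_all)) stop("navigator lines must be sampled at every frame")
  nx <- kspace$grid[1L]; ny <- kspace$grid[2L]
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_along(nav) - 1L) / (length(nav) - 1L))
  low <- matrix(0 + 0i, nx * ny, Nt)
  for (t in seq_len(Nt)) {
    acc <- rep(0 + 0i, nx * ny)
    for (c in seq_len(kspace$coils$n_coils)) {
      k <- matrix(0 + 0i, nx, ny)
      k[, nav] <- kspace$samples[, nav, c, t] * rep(win, each = nx)
      acc <- acc + Conj(kspace$coils$maps[c, ]) * as.vector(ifft2c(k))
    }
    low[, t] <- acc
  }
  sv <- svd(low)
  V <- t(Conj(sv$v[, seq_len(rank), drop = FALSE]))
  b <- new_temporal_basis(V, provenance = "navigator-SVD")
  b$sv <- sv$d / sv$d[1L]
  b
}

#' Temporal basis from a fully known series
#'
#' Top right singular vectors of the Casorati matrix; used for ground-truth
#' subspaces in simulation studies.
#'
#' @param series an `image_series` or Casorati matrix
#' @param rank subspace order
#' @return a `temporal_basis` (provenance `"truth-SVD"`)
#' @export
basis_from_series <- function(series, rank) {
  C <- casorati(series)
  if (rank < 1L || rank > ncol(C)) stop("rank must be between 1 and the number of frames")
  sv <- svd(C)
  b <- new_temporal_basis(t(Conj(sv$v[, seq_len(rank), drop = FALSE])), provenance = "truth-SVD")
  b$sv <- sv$d / sv$d[1L]
  b
}

#' Project a series onto a temporal basis
#'
#' With orthonormal basis rows, `U = C V^H` is the least-squares spatial
#' coefficient matrix and `U V` the rank-R fit of the series.
#'
#' @param series an `image_series` or Casorati matrix
#' @param basis a `temporal_basis` (or bare `R x Nt` matrix)
#' @return complex `N x R` spatial coefficient matrix
#' @export
project_to_subspace <- function(series, basis) {
  C <- casorati(series)
  V <- if (inherits(basis, "temporal_basis")) basis$V else basis
  if (ncol(C) != ncol(V)) stop("series frame count does not match the basis")
  C %*% Conj(t(V))
}
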