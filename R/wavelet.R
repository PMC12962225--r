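# Orthogonal Daubechies-4 (4-tap) periodic 2D wavelet transform.
#
# The sparsifying transform for fat and silicone in the joint reconstruction.
# Orthogonality (periodic boundary, orthonormal filters) keeps the L1 proximal
# step exact: soft-thresholding in the coefficient domain is the exact prox of
# lambda * ||W rho||_1 because W^H W = I.

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)   # quadrature mirror highpass
  list(h = h, g = g)
}

# One periodic analysis level along columns of a matrix (length must be even).
dwt_cols <- function(x, h, g) {
  n <- nrow(x)
  idx <- outer(seq(1L, n, by = 2L), 0:3, function(i, k) ((i + k - 1L) %% n) + 1L)
  lo <- h[1] * x[idx[, 1], , drop = FALSE] + h[2] * x[idx[, 2], , drop = FALSE] +
        h[3] * x[idx[, 3], , drop = FALSE] + h[4] * x[idx[, 4], , drop = FALSE]
  hi <- g[1] * x[idx[, 1], , drop = FALSE] + g[2] * x[idx[, 2], , drop = FALSE] +
        g[3] * x[idx[, 3], , drop = FALSE] + g[4] * x[idx[, 4], , drop = FALSE]
  rbind(lo, hi)
}

idwt_cols <- function(x, h, g) {
  n <- nrow(x)
  half <- n %/% 2L
  lo <- x[seq_len(half), , drop = FALSE]
  hi <- x[half + seq_len(half), , drop = FALSE]
  out <- matrix(0i, n, ncol(x))
  # adjoint of dwt_cols (orthogonal => inverse)
  for (k in 0:3) {
    rows <- ((2L * (seq_len(half) - 1L) + k) %% n) + 1L
    contrib <- h[k + 1] * lo + g[k + 1] * hi
    # rows may repeat only if n < 4; sizes here are >= 8
    out[rows, ] <- out[rows, ] + contrib
  }
  out
}

#' Orthogonal periodic 2D Daubechies-4 wavelet transform
#'
#' @param x complex matrix; both dimensions must be divisible by `2^levels`.
#' @param levels decomposition depth (default 3).
#' @return coefficient matrix of the same shape (approximation in the top-left
#'   `dim/2^levels` block).
#' @export
dwt2 <- function(x, levels = 3L) {
  f <- daub4_filters()
  d <- dim(x)
  if (any(d %% 2L^levels != 0L)) stop("dimensions must be divisible by 2^levels")
  nx <- d[1L]; ny <- d[2L]
  for (l in seq_len(levels)) {
    sub <- x[seq_len(nx), seq_len(ny), drop = FALSE]
    sub <- dwt_cols(sub, f$h, f$g)
    sub <- t(dwt_cols(t(sub), f$h, f$g))
    x[seq_len(nx), seq_len(ny)] <- sub
    nx <- nx %/% 2L; ny <- ny %/% 2L
  }
  x
}

#' Inverse (adjoint) of [dwt2()]
#' @param x coefficient matrix from [dwt2()].
#' @param levels decomposition depth used in the forward transform.
#' @export
idwt2 <- function(x, levels = 3L) {
  f <- daub4_filters()
  d <- dim(x)
  nx <- d[1L] %/% 2L^(levels - 1L); ny <- d[2L] %/% 2L^(levels - 1L)
  for (l in seq_len(levels)) {
    sub <- x[seq_len(nx), seq_len(ny), drop = FALSE]
    sub <- t(idwt_cols(t(sub), f$h, f$g))
    sub <- idwt_cols(sub, f$h, f$g)
    x[seq_len(nx), seq_len(ny)] <- sub
    nx <- nx * 2L; ny <- ny * 2L
  }
  x
}
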