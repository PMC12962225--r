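# Unitary FFT helpers and the subpixel readout shift operator.
#
# All transforms in the package are unitary (1/sqrt(N) both ways) so that every
# operator adjoint equals its inverse where the operator is unitary, and adjoint
# dot-product tests hold to machine precision.

#' Unitary 2D discrete Fourier transform
#'
#' @param x complex matrix (image or k-space plane).
#' @param inverse logical; apply the inverse transform.
#' @return complex matrix of the same shape.
#' @keywords internal
fft2u <- function(x, inverse = FALSE) {
  stats::fft(x, inverse = inverse) / sqrt(length(x))
}

# Unitary 2D FFT applied plane-by-plane to a [Nx, Ny, K] stack in two batched
# mvfft passes (fast path for multi-coil data).
fft2u_stack <- function(a, inverse = FALSE) {
  d <- dim(a)
  if (length(d) == 2L) return(fft2u(a, inverse = inverse))
  nx <- d[1L]; ny <- d[2L]; K <- prod(d[-(1:2)])
  dim(a) <- c(nx, ny * K)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(nx, ny, K)
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(ny, nx * K)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(ny, nx, K)
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- d
  a / sqrt(nx * ny)
}

# Half-FOV circular shift of the first two dims (self-inverse for even sizes);
# converts between FFT-ordered and centered k-space.
kshift2 <- function(x) {
  d <- dim(x)
  stopifnot(d[1L] %% 2L == 0L, d[2L] %% 2L == 0L)
  i1 <- c((d[1L] / 2 + 1L):d[1L], 1:(d[1L] / 2))
  i2 <- c((d[2L] / 2 + 1L):d[2L], 1:(d[2L] / 2))
  if (length(d) == 2L) return(x[i1, i2])
  dim(x) <- c(d[1L], d[2L], prod(d[-(1:2)]))
  x <- x[i1, i2, , drop = FALSE]
  dim(x) <- d
  x
}

# Centered unitary 2D FFT of a [Nx, Ny, ...] stack: DC lands at
# [Nx/2 + 1, Ny/2 + 1]. Unitary, so the adjoint is the inverse.
cfft2u_stack <- function(a, inverse = FALSE) {
  if (inverse) fft2u_stack(kshift2(a), inverse = TRUE)
  else kshift2(fft2u_stack(a))
}

# (-1)^(x+y) checkerboard: for even sizes, multiplying the image by it is
# equivalent to the half-FOV k-space shift (kshift2 after the FFT), which is
# cheaper and lets the modulation be folded into precomputed sensitivities.
checkerboard <- function(nx, ny) {
  outer(seq_len(nx) - 1L, seq_len(ny) - 1L, function(i, j) 1 - 2 * ((i + j) %% 2L))
}

# DFT sample frequencies in FFT order (cycles per array length N).
fft_freqs <- function(n) {
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
}

#' Subpixel circular shift along the readout axis
#'
#' Applies the image-domain displacement operator M(dx): a circular shift of
#' `dx` pixels along the readout (first) dimension, implemented as a Fourier
#' phase ramp. The operator is unitary; `shift_operator(x, -dx)` is its exact
#' inverse and adjoint. Used to model the opposing-direction chemical-shift
#' displacement of off-resonant species under bipolar readout gradients.
#'
#' @param img complex matrix, readout along rows.
#' @param dx signed shift in pixels (may be fractional).
#' @return shifted complex matrix.
#' @export
shift_operator <- function(img, dx) {
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx)) {
    stop("`dx` must be a single finite number")
  }
  if (dx == 0) return(img)
  nx <- nrow(img)
  ramp <- exp(-2i * pi * fft_freqs(nx) * dx / nx)
  stats::mvfft(stats::mvfft(img) * ramp, inverse = TRUE) / nx
}

# Run `expr` with a deterministic, locally-scoped RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Complex white Gaussian array, unit variance per complex sample.
crandn <- function(dims) {
  n <- prod(dims)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
  array(z, dims)
}

# Binary erosion of a logical matrix by a (2r+1)x(2r+1) square element.
erode_mask <- function(m, r = 1L) {
  m <- m * 1
  for (i in seq_len(r)) {
    p <- rbind(0, cbind(0, m, 0), 0)
    nx <- nrow(m); ny <- ncol(m)
    acc <- matrix(1, nx, ny)
    for (dx in -1:1) for (dy in -1:1) {
      acc <- acc * p[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
    }
    m <- acc
  }
  m > 0
}

# Normalized root-mean-square error between complex arrays.
nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
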