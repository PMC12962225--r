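# The joint forward operator E: species images -> stacked multi-polarity,
# multi-echo, multi-coil k-space, and its exact adjoint.
#
# Composition (right to left, per polarity +/-):
#   D+- F S+- A(mu) M+-
# i.e. per-species subpixel readout shift (opposing directions for the two
# polarities), chemical-shift encoding with the field estimate mu, coil/ghost
# sensitivities per polarity, unitary 2D DFT, and the ky sampling masks.
# Every factor's adjoint is exact (unitary FFT and shifts, conjugate
# multiplications, real binary masks), so the operator passes adjoint
# dot-product tests to near machine precision. The k-space simulator uses this
# same operator, which makes simulation and reconstruction model-matched by
# construction.

#' Chemical-shift displacement set
#'
#' Signed readout displacements (pixels) of fat and silicone for the positive
#' polarity; the negative polarity uses the negated values. Fat uses the
#' amplitude-weighted mean fat frequency as a single bulk shift.
#'
#' @param model a `spectral_model`.
#' @param pixel_bandwidth_hz readout bandwidth per pixel (Hz/pixel).
#' @return object of class `shift_set` with `dx_fat`, `dx_sil`.
#' @export
shift_set <- function(model, pixel_bandwidth_hz = 1000) {
  stopifnot(pixel_bandwidth_hz > 0)
  shift_set_manual(fat_mean_freq_hz(model) / pixel_bandwidth_hz,
                   silicone_freq_hz(model) / pixel_bandwidth_hz)
}

#' @rdname shift_set
#' @param dx_fat,dx_sil explicit displacements in pixels.
#' @export
shift_set_manual <- function(dx_fat, dx_sil) {
  stopifnot(is.finite(dx_fat), is.finite(dx_sil))
  structure(list(dx_fat = dx_fat, dx_sil = dx_sil), class = "shift_set")
}

#' Polarity-resolved coil sensitivities
#'
#' @param s_pos,s_neg complex arrays `[Nx, Ny, n_coils]` for the positive and
#'   negative readout polarities (Nyquist ghost phase absorbed).
#' @param method character tag recording how the maps were obtained.
#' @export
polarity_sens <- function(s_pos, s_neg, method = "manual") {
  if (length(dim(s_pos)) == 2L) dim(s_pos) <- c(dim(s_pos), 1L)
  if (length(dim(s_neg)) == 2L) dim(s_neg) <- c(dim(s_neg), 1L)
  stopifnot(all(dim(s_pos) == dim(s_neg)))
  structure(list(s_pos = s_pos, s_neg = s_neg, method = method,
                 n_coils = dim(s_pos)[3L]),
            class = "polarity_sens")
}

# encode species -> per-echo images for one polarity (A(mu) M);
# emu is the precomputed list of exp(mu * t_j) maps
encode_polarity <- function(rho, emu, a0, n_echoes, shifts, pol_sign) {
  rw <- rho$w
  rf <- if (shifts$dx_fat != 0) shift_operator(rho$f, pol_sign * shifts$dx_fat) else rho$f
  rs <- if (shifts$dx_sil != 0) shift_operator(rho$s, pol_sign * shifts$dx_sil) else rho$s
  out <- array(0i, c(dim(rw), n_echoes))
  for (j in seq_len(n_echoes)) {
    out[, , j] <- emu[[j]] * (rw + a0[j, 2L] * rf + a0[j, 3L] * rs)
  }
  out
}

# exact adjoint of encode_polarity
decode_polarity_adj <- function(ech, cemu, a0, n_echoes, shifts, pol_sign) {
  d <- dim(ech)[1:2]
  w <- matrix(0i, d[1], d[2]); f <- w; s <- w
  for (j in seq_len(n_echoes)) {
    cj <- cemu[[j]] * ech[, , j]
    w <- w + cj
    f <- f + Conj(a0[j, 2L]) * cj
    s <- s + Conj(a0[j, 3L]) * cj
  }
  if (shifts$dx_fat != 0) f <- shift_operator(f, -pol_sign * shifts$dx_fat)
  if (shifts$dx_sil != 0) s <- shift_operator(s, -pol_sign * shifts$dx_sil)
  list(w = w, f = f, s = s)
}

#' Build the joint reconstruction operator
#'
#' @param field a `field_params` (the mu estimate used by the model).
#' @param sens a `polarity_sens`.
#' @param pattern a `sampling_pattern`.
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @param shifts a `shift_set`.
#' @return object of class `wfs_operator`: list with `forward(rho)` mapping a
#'   `species_images` to k-space `[Nx, Ny, n_coils, Nt, 2]`, the exact
#'   `adjoint(y)`, `normal(rho)` = adjoint(forward(rho)), and `dims`.
#' @export
build_joint_operator <- function(field, sens, pattern, times, model, shifts) {
  nx <- dim(sens$s_pos)[1L]; ny <- dim(sens$s_pos)[2L]
  nc <- sens$n_coils
  if (!all(dim(field$mu) == c(nx, ny))) stop("field/sensitivity shape mismatch")
  if (pattern$n_ky != ny) stop("pattern ky size must equal Ny")
  if (pattern$n_echoes != times$n) stop("pattern/echo count mismatch")
  nt <- times$n
  mu <- field$mu
  a0 <- encoding_basis(times, model)
  emu <- lapply(seq_len(nt), function(j) exp(mu * times$t[j]))
  cemu <- lapply(emu, Conj)
  # per-(echo, polarity) mask planes, recycled over coils
  mvec <- vector("list", 2L)
  for (p in 1:2) {
    mvec[[p]] <- lapply(seq_len(nt), function(j)
      rep(pattern$mask[, j, p], each = nx))
  }
  sgn <- c(1, -1)
  # fold the centered-FFT checkerboard modulation into the sensitivities
  chk <- as.vector(checkerboard(nx, ny))
  Sc <- list(sens$s_pos * chk, sens$s_neg * chk)
  CSc <- list(Conj(sens$s_pos) * chk, Conj(sens$s_neg) * chk)

  forward <- function(rho) {
    y <- array(0i, c(nx, ny, nc, nt, 2L))
    for (p in 1:2) {
      ech <- encode_polarity(rho, emu, a0, nt, shifts, sgn[p])
      for (j in seq_len(nt)) {
        k <- fft2u_stack(Sc[[p]] * as.vector(ech[, , j]))
        y[, , , j, p] <- k * mvec[[p]][[j]]
      }
    }
    y
  }

  adjoint <- function(y) {
    acc <- NULL
    for (p in 1:2) {
      ech <- array(0i, c(nx, ny, nt))
      for (j in seq_len(nt)) {
        img <- fft2u_stack(y[, , , j, p, drop = FALSE] * mvec[[p]][[j]],
                           inverse = TRUE)
        dim(img) <- c(nx, ny, nc)
        ech[, , j] <- rowSums(CSc[[p]] * img, dims = 2L)
      }
      part <- decode_polarity_adj(ech, cemu, a0, nt, shifts, sgn[p])
      acc <- if (is.null(acc)) part else
        list(w = acc$w + part$w, f = acc$f + part$f, s = acc$s + part$s)
    }
    species_images(acc$w, acc$f, acc$s)
  }

  structure(list(forward = forward, adjoint = adjoint,
                 normal = function(rho) adjoint(forward(rho)),
                 dims = list(nx = nx, ny = ny, n_coils = nc, n_echoes = nt),
                 times = times, model = model, shifts = shifts,
                 pattern = pattern),
            class = "wfs_operator")
}

# Largest eigenvalue of E^H E by power iteration (Lipschitz constant of the
# data-term gradient), deterministic start.
operator_lipschitz <- function(E, n_iter = 15L) {
  d <- E$dims
  v <- with_local_seed(42L, {
    species_images(crandn(c(d$nx, d$ny)), crandn(c(d$nx, d$ny)),
                   crandn(c(d$nx, d$ny)))
  })
  lam <- 1
  for (i in seq_len(n_iter)) {
    nv <- E$normal(v)
    lam <- sqrt(sum(Mod(nv$w)^2 + Mod(nv$f)^2 + Mod(nv$s)^2))
    if (lam == 0) return(1)
    v <- species_images(nv$w / lam, nv$f / lam, nv$s / lam)
  }
  lam
}
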