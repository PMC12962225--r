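# Nyquist ghost correction by polarity stacking.
#
# Bipolar readouts carry a smooth polarity-dependent phase difference that
# aliases as a Nyquist ghost once the two polarities sample complementary ky
# lines. Stacking positive- and negative-polarity data along the coil
# dimension turns the ghost phase into part of an extended 2*n_coils
# sensitivity set, which ESPIRiT can calibrate from the fully sampled ACS
# block; a SENSE-like solve with the stacked maps then reconstructs
# ghost-corrected echo images.

# Central calibration block [ckx, cky, channels] from stacked ACS k-space.
calib_block <- function(k_stacked, n_acs, ckx = 32L) {
  d <- dim(k_stacked)
  rows <- acs_rows(d[1L], min(d[1L], ckx))
  cols <- acs_rows(d[2L], n_acs)
  k_stacked[rows, cols, , drop = FALSE]
}

#' Estimate polarity-resolved sensitivities from ACS data
#'
#' `espirit_stacked` (default): builds the block-Hankel calibration matrix
#' from the 2*n_coils stacked channels of the central (spin-echo) echo,
#' SVD-thresholds the row space into kernels, eigen-decomposes the resulting
#' per-pixel operator and keeps the dominant eigenvector as the stacked
#' sensitivity, phase-referenced to the first positive-readout channel and
#' cropped where the eigenvalue falls below `eig_crop`. `acs_phase_diff`:
#' forms low-resolution per-polarity coil-combined images against reference
#' coil maps, smooths their phase difference and applies half of it to each
#' polarity of the reference maps (cheap fallback and cross-check).
#'
#' @param kdata a `kspace_data` whose ACS block is fully sampled in both
#'   polarities, or a complex array `[Nx, Ny, n_coils, Nt, 2]`.
#' @param n_acs width of the fully sampled central ky block.
#' @param method `"espirit_stacked"` or `"acs_phase_diff"`.
#' @param echo index of the echo used for calibration (default: central).
#' @param kernel ESPIRiT kernel size (pixels, square).
#' @param sv_thresh singular-value threshold relative to the largest.
#' @param eig_crop eigenvalue crop threshold.
#' @param ref_coils reference coil maps `[Nx, Ny, n_coils]`, required for
#'   `acs_phase_diff`.
#' @return a `polarity_sens` with attribute `eigval` (espirit method).
#' @export
estimate_polarity_sensitivities <- function(kdata, n_acs = NULL,
                                            method = c("espirit_stacked", "acs_phase_diff"),
                                            echo = NULL, kernel = 6L,
                                            sv_thresh = 0.02, eig_crop = 0.9,
                                            ref_coils = NULL) {
  method <- match.arg(method)
  y <- if (inherits(kdata, "kspace_data")) kdata$y else kdata
  if (is.null(n_acs)) {
    if (!inherits(kdata, "kspace_data")) stop("n_acs required for raw arrays")
    n_acs <- kdata$pattern$n_acs
  }
  d <- dim(y)
  nx <- d[1L]; ny <- d[2L]; nc <- d[3L]; nt <- d[4L]
  if (is.null(echo)) echo <- (nt + 1L) %/% 2L
  # stacked channels: positive polarity coils first, then negative
  kst <- array(0i, c(nx, ny, 2L * nc))
  kst[, , seq_len(nc)] <- y[, , , echo, 1L]
  kst[, , nc + seq_len(nc)] <- y[, , , echo, 2L]

  if (method == "acs_phase_diff") {
    if (is.null(ref_coils)) stop("acs_phase_diff requires `ref_coils`")
    sens <- acs_phase_diff_sens(kst, n_acs, ref_coils)
    return(sens)
  }
  espirit_sens(kst, n_acs, kernel, sv_thresh, eig_crop)
}

acs_phase_diff_sens <- function(kst, n_acs, ref_coils) {
  d <- dim(kst); nx <- d[1L]; ny <- d[2L]; nc <- d[3L] %/% 2L
  # low-resolution images from the ACS lines (apodized to tame ringing)
  win <- matrix(0, nx, ny)
  cols <- acs_rows(ny, n_acs)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_along(cols) / (length(cols) + 1))
  win[, cols] <- rep(han, each = nx)
  imgs <- cfft2u_stack(kst * as.vector(win), inverse = TRUE)
  combine <- function(idx) {
    rowSums(Conj(ref_coils) * imgs[, , idx, drop = FALSE], dims = 2L)
  }
  ip <- combine(seq_len(nc)); im <- combine(nc + seq_len(nc))
  diffmap <- ip * Conj(im)
  diffmap <- smooth2(Re(diffmap), 3) + 1i * smooth2(Im(diffmap), 3)
  phi <- Arg(diffmap)   # full positive-minus-negative phase difference
  half <- exp(0.5i * phi)
  s_pos <- ref_coils * as.vector(half)
  s_neg <- ref_coils * as.vector(Conj(half))
  rss <- sqrt(rowSums(Mod(s_pos)^2 + Mod(s_neg)^2, dims = 2L))
  rss[rss == 0] <- 1
  sens <- polarity_sens(s_pos / as.vector(rss), s_neg / as.vector(rss),
                        method = "acs_phase_diff")
  attr(sens, "phase_diff") <- phi
  sens
}

# moving-average smoother (box of half-width r, replicate edges)
smooth2 <- function(x, r = 2L) {
  n1 <- nrow(x); n2 <- ncol(x)
  pad <- x[c(rep(1L, r), seq_len(n1), rep(n1, r)),
           c(rep(1L, r), seq_len(n2), rep(n2, r))]
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  sm <- apply(pad, 2L, function(col) stats::filter(col, k, sides = 2L))
  sm <- t(apply(sm, 1L, function(row) stats::filter(row, k, sides = 2L)))
  sm[r + seq_len(n1), r + seq_len(n2)]
}

espirit_sens <- function(kst, n_acs, kernel = 6L, sv_thresh = 0.02,
                         eig_crop = 0.9) {
  d <- dim(kst); nx <- d[1L]; ny <- d[2L]; ncs <- d[3L]
  calib <- calib_block(kst, n_acs)
  cd <- dim(calib)
  if (cd[1L] < kernel || cd[2L] < kernel) stop("ACS region too small for kernel")
  nwx <- cd[1L] - kernel + 1L; nwy <- cd[2L] - kernel + 1L
  # block-Hankel calibration matrix: rows = sliding windows
  A <- matrix(0i, nwx * nwy, kernel * kernel * ncs)
  r <- 1L
  for (wy in seq_len(nwy)) for (wx in seq_len(nwx)) {
    A[r, ] <- as.vector(calib[wx:(wx + kernel - 1L), wy:(wy + kernel - 1L), ])
    r <- r + 1L
  }
  sv <- svd(A)
  keep <- which(sv$d >= sv_thresh * sv$d[1L])
  # conjugated row-space kernels: the per-pixel dominant eigenvector of the
  # resulting Gram operator is then the sensitivity itself (not its conjugate)
  V <- Conj(sv$v[, keep, drop = FALSE])
  nk <- length(keep)
  # image-domain kernels: zero-pad each kernel channel to [nx, ny] and
  # inverse-transform; scaling sqrt(nx*ny)/kernel makes the dominant
  # eigenvalue ~1 inside the object support
  Gimg <- array(0i, c(nx, ny, ncs, nk))
  padx <- (nx - kernel) %/% 2L; pady <- (ny - kernel) %/% 2L
  for (i in seq_len(nk)) {
    ker <- array(V[, i], c(kernel, kernel, ncs))
    kp <- array(0i, c(nx, ny, ncs))
    kp[padx + seq_len(kernel), pady + seq_len(kernel), ] <- ker
    Gimg[, , , i] <- cfft2u_stack(kp, inverse = TRUE) * sqrt(nx * ny) / kernel
  }
  # per-pixel Gram matrix M(r) = sum_i g_i g_i^H and dominant eigenvector
  sens <- array(0i, c(nx, ny, ncs))
  eigval <- matrix(0, nx, ny)
  Gm <- matrix(Gimg, nx * ny, ncs * nk)
  for (px in seq_len(nx * ny)) {
    Gq <- matrix(Gm[px, ], ncs, nk)
    M <- Gq %*% Conj(t(Gq))
    e <- eigen(M, symmetric = TRUE)
    eigval[px] <- e$values[1L]
    v <- e$vectors[, 1L]
    # phase reference: first positive-readout channel
    v <- v * exp(-1i * Arg(v[1L]))
    sens[px + (seq_len(ncs) - 1L) * nx * ny] <- v
  }
  crop <- eigval >= eig_crop
  sens <- sens * as.vector(crop)
  nc <- ncs %/% 2L
  out <- polarity_sens(sens[, , seq_len(nc), drop = FALSE],
                       sens[, , nc + seq_len(nc), drop = FALSE],
                       method = "espirit_stacked")
  attr(out, "eigval") <- eigval
  out
}

#' Nyquist-ghost-corrected SENSE reconstruction of echo images
#'
#' Solves the stacked-polarity normal equations per echo by conjugate
#' gradients: `argmin_x || [D+ F S+; D- F S-] x - [y+; y-] ||^2`.
#'
#' @param kdata a `kspace_data`.
#' @param sens a `polarity_sens`.
#' @param tol relative residual tolerance of the CG solve.
#' @param max_iter CG iteration cap.
#' @param warn warn when an echo stops above `tol` (disable for least-squares
#'   problems whose minimum residual is inherently nonzero, e.g. apodized
#'   ACS data).
#' @return complex array `[Nx, Ny, Nt]` of ghost-corrected echo images, with
#'   attribute `residuals` (final relative residual per echo).
#' @export
ngc_sense <- function(kdata, sens, tol = 1e-9, max_iter = 50L, warn = TRUE) {
  y <- kdata$y
  d <- dim(y)
  nx <- d[1L]; ny <- d[2L]; nc <- d[3L]; nt <- d[4L]
  stopifnot(all(dim(sens$s_pos)[1:2] == c(nx, ny)), sens$n_coils == nc)
  pattern <- kdata$pattern
  S <- list(sens$s_pos, sens$s_neg)
  out <- array(0i, c(nx, ny, nt))
  res <- numeric(nt)
  for (j in seq_len(nt)) {
    mv <- lapply(1:2, function(p) rep(pattern$mask[, j, p], each = nx))
    Aop <- function(x) {   # normal operator for echo j
      acc <- matrix(0i, nx, ny)
      for (p in 1:2) {
        k <- cfft2u_stack(S[[p]] * as.vector(x)) * mv[[p]]
        img <- cfft2u_stack(k, inverse = TRUE)
        acc <- acc + rowSums(Conj(S[[p]]) * img, dims = 2L)
      }
      acc
    }
    b <- matrix(0i, nx, ny)
    for (p in 1:2) {
      img <- cfft2u_stack(y[, , , j, p, drop = FALSE] * mv[[p]], inverse = TRUE)
      dim(img) <- c(nx, ny, nc)
      b <- b + rowSums(Conj(S[[p]]) * img, dims = 2L)
    }
    cg <- cg_solve(Aop, b, tol = tol, max_iter = max_iter)
    out[, , j] <- cg$x
    res[j] <- cg$rel_res
    if (warn && cg$rel_res > tol && max(Mod(b)) > 0) {
      warning(sprintf("echo %d: CG stopped at relative residual %.2e", j, cg$rel_res))
    }
  }
  attr(out, "residuals") <- res
  out
}

# plain conjugate gradients on a Hermitian PSD operator
cg_solve <- function(Aop, b, x0 = NULL, tol = 1e-9, max_iter = 50L) {
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - Aop(x)
  p <- r
  rs <- sum(Mod(r)^2)
  b2 <- sum(Mod(b)^2)
  if (b2 == 0) return(list(x = x, rel_res = 0, iters = 0L))
  for (i in seq_len(max_iter)) {
    Ap <- Aop(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (denom <= 0) break
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    if (sqrt(rs_new / b2) < tol) { rs <- rs_new; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, rel_res = sqrt(rs / b2), iters = i)
}

#' Ghost-to-signal ratio of an image
#'
#' Mean magnitude inside the Nyquist-shifted replica zone (the object support
#' shifted by half the FOV along ky, minus the support) over the mean
#' magnitude inside the support.
#'
#' @param img complex image.
#' @param support logical object-support mask.
#' @export
ghost_to_signal <- function(img, support) {
  ny <- ncol(support)
  shifted <- support[, ((seq_len(ny) - 1L + ny %/% 2L) %% ny) + 1L]
  zone <- shifted & !support
  mean(Mod(img[zone])) / mean(Mod(img[support]))
}
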