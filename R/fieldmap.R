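# Field and R2' mapping from multi-echo images.
#
# The off-resonance map fB is found by a discrete candidate search on a
# VARPRO-style residual (species amplitudes eliminated analytically, leaving a
# cost over fB alone) with an L1 spatial smoothness prior, optimized by
# checkerboard iterated conditional modes (ICM) with multiple starts, then
# refined per pixel by a local quadratic fit. This is a deliberate single-layer
# simplification of graph-cut water-fat field mapping: its contract is correct
# recovery on smooth field maps, not parity with multi-layer solvers on
# pathological in-vivo data. R2' is fit afterwards per pixel with mu held at
# 2*pi*i*fB - r2p.

#' Field-map candidate grid
#'
#' @param f_max half-range of the search in Hz (grid covers `[-f_max, f_max]`).
#' @param delta_f grid spacing in Hz (default 2, at most 5).
#' @param smoothness_weight weight of the L1 neighbor penalty, in units of the
#'   normalized data residual per Hz.
#' @return object of class `field_candidates`.
#' @export
field_candidates <- function(f_max = 300, delta_f = 2, smoothness_weight = 2e-3) {
  stopifnot(f_max > 0, delta_f > 0, delta_f <= 5, smoothness_weight >= 0)
  structure(list(grid = seq(-f_max, f_max, by = delta_f),
                 f_max = f_max, delta_f = delta_f,
                 smoothness_weight = smoothness_weight),
            class = "field_candidates")
}

#' VARPRO residual of one pixel at a candidate off-resonance
#'
#' Squared norm of the echo vector component orthogonal to the column space of
#' the encoding matrix at `fB_cand` (R2' = 0): `||(I - A A^+) x||^2`.
#'
#' @param echoes_px complex vector of `Nt` echo samples for one pixel.
#' @param fB_cand candidate off-resonance in Hz.
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @return nonnegative scalar.
#' @export
varpro_residual <- function(echoes_px, fB_cand, times, model) {
  x <- as.vector(echoes_px)
  A <- encoding_matrix(2i * pi * fB_cand, times, model)
  coef <- solve(Conj(t(A)) %*% A, Conj(t(A)) %*% x)
  sum(Mod(x - drop(A %*% coef))^2)
}

# Residual matrix [Npix, Ncand] for all pixels and candidates (vectorized).
varpro_residual_all <- function(X, grid, times, model) {
  npx <- nrow(X)
  out <- matrix(0, npx, length(grid))
  for (ci in seq_along(grid)) {
    A <- encoding_matrix(2i * pi * grid[ci], times, model)
    P <- A %*% solve(Conj(t(A)) %*% A, Conj(t(A)))   # projector onto col(A)
    resid <- X - X %*% t(P)                           # rows are pixel vectors
    out[, ci] <- rowSums(Mod(resid)^2)
  }
  out
}

#' Estimate the off-resonance field map
#'
#' Discrete minimization of `sum_p residual(fB(p)) + w * sum_<pq> |fB(p)-fB(q)|`
#' over the candidate grid by checkerboard ICM from two starts (per-pixel
#' argmin and its median-filtered version; the lower-energy result wins, which
#' also provides the smoothness-favoring tie-break), followed by per-pixel
#' quadratic refinement of fB between neighboring grid points. Deterministic.
#'
#' @param echoes complex array `[Nx, Ny, Nt]` (typically ACS-resolution).
#' @param cands a [field_candidates()].
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @param n_sweeps ICM sweeps per start.
#' @return a `field_params` with `fB` filled and `r2p = 0`, attribute
#'   `label` (grid index map) and `energy`.
#' @export
estimate_fieldmap <- function(echoes, cands, times, model, n_sweeps = 12L) {
  d <- dim(echoes)
  nx <- d[1L]; ny <- d[2L]
  X <- matrix(echoes, nx * ny, d[3L])
  R <- varpro_residual_all(X, cands$grid, times, model)
  pw <- mean(rowSums(Mod(X)^2))
  if (pw > 0) R <- R / pw
  w <- cands$smoothness_weight
  grid <- cands$grid
  ncand <- length(grid)
  # signal-free pixels have a flat residual: give them no data preference so
  # the smoothness term (and the centered init) decides, and keep them out of
  # the grid-edge diagnostics
  weak <- rowSums(Mod(X)^2) < 1e-6 * pw
  R[weak, ] <- 0

  icm <- function(lab) {
    labm <- matrix(lab, nx, ny)
    parity <- (outer(seq_len(nx), seq_len(ny), "+")) %% 2L
    for (s in seq_len(n_sweeps)) {
      changed <- FALSE
      for (col in 0:1) {
        f_now <- matrix(grid[labm], nx, ny)
        nb <- neighbor_stack(f_now)
        upd <- parity == col
        cost_best <- rep(Inf, sum(upd))
        lab_best <- integer(sum(upd))
        Rsub <- R[as.vector(upd), , drop = FALSE]
        for (ci in seq_len(ncand)) {
          pen <- nb$count * 0
          for (k in 1:4) pen <- pen + abs(grid[ci] - nb$vals[[k]]) * nb$ok[[k]]
          cost <- Rsub[, ci] + w * pen[upd]
          better <- cost < cost_best
          cost_best[better] <- cost[better]
          lab_best[better] <- ci
        }
        if (any(labm[upd] != lab_best)) changed <- TRUE
        labm[upd] <- lab_best
      }
      if (!changed) break
    }
    f_now <- matrix(grid[labm], nx, ny)
    nb <- neighbor_stack(f_now)
    pen <- f_now * 0
    for (k in 1:4) pen <- pen + abs(f_now - nb$vals[[k]]) * nb$ok[[k]]
    energy <- sum(R[cbind(seq_len(nx * ny), as.vector(labm))]) +
      w * sum(pen) / 2
    list(lab = labm, energy = energy)
  }

  lab0 <- max.col(-R, ties.method = "first")
  lab0[weak] <- (ncand + 1L) %/% 2L
  # multi-start: per-pixel argmin, its median-filtered version, and the
  # median-filtered first result (removes small ICM-stable ambiguity islands,
  # whose single-pixel flips are smoothness-neutral); lowest energy wins
  start1 <- icm(lab0)
  start2 <- icm(as.vector(median_filter3(matrix(lab0, nx, ny))))
  start3 <- icm(as.vector(median_filter3(median_filter3(start1$lab))))
  starts <- list(start1, start2, start3)
  best <- starts[[which.min(vapply(starts, `[[`, numeric(1), "energy"))]]
  labm <- best$lab

  edge <- mean((labm == 1L | labm == ncand)[!weak])
  if (edge >= 0.01) {
    warning(sprintf("%.1f%% of pixels at the candidate grid edge; widen f_max",
                    100 * edge))
  }

  # local quadratic refinement between grid neighbors
  fB <- matrix(grid[labm], nx, ny)
  idx <- as.vector(labm)
  interior <- idx > 1L & idx < ncand
  px <- which(interior)
  if (length(px) > 0L) {
    r0 <- R[cbind(px, idx[px] - 1L)]
    r1 <- R[cbind(px, idx[px])]
    r2 <- R[cbind(px, idx[px] + 1L)]
    denom <- r0 - 2 * r1 + r2
    step <- ifelse(denom > 0, 0.5 * (r0 - r2) / denom, 0)
    step <- pmax(-1, pmin(1, step))
    fB[px] <- fB[px] + step * cands$delta_f
  }
  out <- field_params(fB, 0)
  attr(out, "label") <- labm
  attr(out, "energy") <- best$energy
  out
}

# 4-neighbor values with validity masks (non-periodic boundaries)
neighbor_stack <- function(f) {
  nx <- nrow(f); ny <- ncol(f)
  shift <- function(dx, dy) {
    v <- matrix(0, nx, ny); ok <- matrix(0, nx, ny)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    vx <- xs >= 1 & xs <= nx; vy <- ys >= 1 & ys <= ny
    v[vx, vy] <- f[xs[vx], ys[vy]]
    ok[vx, vy] <- 1
    list(v = v, ok = ok)
  }
  s <- list(shift(1, 0), shift(-1, 0), shift(0, 1), shift(0, -1))
  list(vals = lapply(s, `[[`, "v"), ok = lapply(s, `[[`, "ok"),
       count = Reduce(`+`, lapply(s, `[[`, "ok")))
}

median_filter3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- m[c(1L, seq_len(nx), nx), c(1L, seq_len(ny), ny)]
  stack <- array(0, c(nx, ny, 9L))
  i <- 1L
  for (dx in 0:2) for (dy in 0:2) {
    stack[, , i] <- p[dx + seq_len(nx), dy + seq_len(ny)]
    i <- i + 1L
  }
  matrix(as.integer(apply(stack, c(1, 2), stats::median)), nx, ny)
}

#' Estimate the R2' map given the field map
#'
#' Per pixel, searches r2p in `[0, r2p_max]` minimizing the model residual at
#' `mu = 2*pi*i*fB - r2p` (discrete grid, fully vectorized across pixels,
#' followed by per-pixel parabolic refinement), and recomputes `mu`.
#'
#' @param echoes complex array `[Nx, Ny, Nt]`.
#' @param field a `field_params` with `fB` estimated.
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @param r2p_max upper bound in 1/s (default 100).
#' @param step grid step in 1/s.
#' @return a `field_params` with both `fB` and `r2p` filled.
#' @export
estimate_r2prime <- function(echoes, field, times, model,
                             r2p_max = 100, step = 1) {
  d <- dim(echoes)
  npx <- d[1L] * d[2L]
  X <- matrix(echoes, npx, d[3L])
  fB <- as.vector(field$fB)
  grid <- seq(0, r2p_max, by = step)
  Rmat <- matrix(0, npx, length(grid))
  e2 <- rowSums(Mod(X)^2)
  for (gi in seq_along(grid)) {
    mu <- complex(real = -grid[gi], imaginary = 2 * pi * fB)
    sol <- solve_species_px(X, mu, times, model)
    # residual = ||x||^2 - Re(b^H rho)
    fitq <- Re(rowSums(Conj(sol$b) * sol$rho))
    Rmat[, gi] <- pmax(0, e2 - fitq)
  }
  idx <- max.col(-Rmat, ties.method = "first")
  r2p <- grid[idx]
  interior <- idx > 1L & idx < length(grid)
  px <- which(interior)
  if (length(px) > 0L) {
    r0 <- Rmat[cbind(px, idx[px] - 1L)]
    r1 <- Rmat[cbind(px, idx[px])]
    r2 <- Rmat[cbind(px, idx[px] + 1L)]
    denom <- r0 - 2 * r1 + r2
    adj <- ifelse(denom > 0, 0.5 * (r0 - r2) / denom, 0)
    r2p[px] <- r2p[px] + pmax(-1, pmin(1, adj)) * step
  }
  r2p <- pmin(pmax(r2p, 0), r2p_max)
  field_params(field$fB, matrix(r2p, d[1L], d[2L]))
}

#' Low-resolution echo images from the ACS block
#'
#' Ghost-corrected SENSE reconstruction restricted to the fully sampled ACS
#' lines, Hann-apodized along ky to suppress truncation ringing in the
#' low-resolution images that feed the field mapping.
#'
#' @param kdata a `kspace_data`.
#' @param sens a `polarity_sens`.
#' @return complex array `[Nx, Ny, Nt]` of low-resolution echo images.
#' @export
acs_echo_images <- function(kdata, sens) {
  n_acs <- kdata$pattern$n_acs
  ny <- dim(kdata$y)[2L]
  keep <- acs_rows(ny, n_acs)
  macs <- array(0, dim(kdata$pattern$mask))
  macs[keep, , ] <- 1
  win <- rep(0, ny)
  win[keep] <- 0.5 - 0.5 * cos(2 * pi * seq_along(keep) / (length(keep) + 1))
  kd <- kdata
  kd$y <- kdata$y * mask_array_like(kdata, macs) *
    rep(rep(win, each = dim(kdata$y)[1L]), prod(dim(kdata$y)[3:5]))
  kd$pattern <- new_sampling_pattern(macs, n_acs, ny / n_acs, "acs_only",
                                     NA_integer_)
  ngc_sense(kd, sens, tol = 1e-7, max_iter = 40L, warn = FALSE)
}

#' Field and R2' maps from the ACS block of an acquisition
#'
#' Pipeline helper: apodized low-resolution ACS reconstruction, discrete fB
#' search, R2' fit, and spatial box smoothing of both maps (the acquisition's
#' field mapping is intrinsically low-resolution, and the true maps are
#' smooth, so smoothing suppresses estimation noise from residual ringing).
#'
#' @param kdata a `kspace_data` with a fully sampled ACS block.
#' @param sens a `polarity_sens`.
#' @param times an `echo_times`.
#' @param model a `spectral_model`.
#' @param cands a [field_candidates()].
#' @param smooth_radius half-width of the box smoother in pixels (0 disables).
#' @return a `field_params` with both `fB` and `r2p` filled.
#' @export
estimate_field_from_acs <- function(kdata, sens, times, model,
                                    cands = field_candidates(),
                                    smooth_radius = 3L) {
  imgs <- acs_echo_images(kdata, sens)
  field <- estimate_fieldmap(imgs, cands, times, model)
  field <- estimate_r2prime(imgs, field, times, model)
  if (smooth_radius > 0L) {
    field <- field_params(smooth2(field$fB, smooth_radius),
                          pmax(smooth2(field$r2p, smooth_radius), 0))
  }
  field
}

mask_array_like <- function(kdata, mask) {
  d <- dim(kdata$y)
  m <- array(0, d)
  for (p in 1:2) for (j in seq_len(d[4L])) {
    m[, , , j, p] <- rep(rep(mask[, j, p], each = d[1L]), d[3L])
  }
  m
}

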