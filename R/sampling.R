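# ky-TE undersampling pattern design: uniform, variable-density and incoherent
# ky-TE (trajectory-based) masks with autocalibration (ACS) bookkeeping, plus
# point-spread-function analysis.
#
# A pattern is a binary [Nky, Nt, 2] tensor; the third index is the readout
# polarity (1 = positive/standard, 2 = negative/flipped). The central n_acs
# ky lines are fully sampled at every echo and both polarities. Acceleration
# accounting is for the combined positive+negative data: a fully sampled
# acquisition has Nky * Nt * 2 lines, and the per-echo combined line budget at
# nominal R is 2*Nky/R INCLUDING the ACS block, so the achieved acceleration
# tracks the nominal one.

new_sampling_pattern <- function(mask, n_acs, R_nominal, kind, seed,
                                 trajectories = NULL, max_jump = NA_real_) {
  storage.mode(mask) <- "double"
  structure(list(mask = mask,
                 n_ky = dim(mask)[1L], n_echoes = dim(mask)[2L],
                 n_acs = as.integer(n_acs), R_nominal = R_nominal,
                 R_achieved = length(mask) / max(1, sum(mask)),
                 kind = kind, seed = seed,
                 trajectories = trajectories, max_jump = max_jump),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf("%s sampling: Nky=%d, Nt=%d, R nominal=%.3g achieved=%.3g, ACS=%d\n",
              x$kind, x$n_ky, x$n_echoes, x$R_nominal, x$R_achieved, x$n_acs))
  invisible(x)
}

acs_rows <- function(n_ky, n_acs) {
  if (n_acs <= 0L) return(integer(0))
  start <- (n_ky - n_acs) %/% 2L + 1L
  seq.int(start, start + n_acs - 1L)
}

# per-echo per-polarity line budget including ACS
lines_per_echo <- function(n_ky, R) max(1L, round(n_ky / R))

#' Uniform (regular) ky undersampling
#'
#' Outside the ACS block, ky lines are sampled at a regular pitch, identical
#' for all echoes within a polarity, with a complementary offset between the
#' two polarities. With `n_acs = 0` this is exactly every-R-th-line sampling;
#' with an ACS block the outer pitch widens so the total per-echo line count
#' stays at `Nky / R`.
#'
#' @param n_ky number of phase-encode lines.
#' @param n_echoes echoes per spin echo.
#' @param R nominal combined acceleration factor (>= 1).
#' @param n_acs fully sampled central lines (both polarities, all echoes).
#' @return a `sampling_pattern`.
#' @export
make_uniform <- function(n_ky, n_echoes, R, n_acs = 0L) {
  stopifnot(R >= 1, R <= n_ky, n_acs >= 0L, n_acs <= n_ky)
  mask <- array(0, c(n_ky, n_echoes, 2L))
  acs <- acs_rows(n_ky, n_acs)
  if (R == 1) {
    mask[] <- 1
    return(new_sampling_pattern(mask, n_acs, R, "uniform", NA_integer_))
  }
  budget <- lines_per_echo(n_ky, R)
  outer_rows <- setdiff(seq_len(n_ky), acs)
  n_outer <- max(0L, budget - length(acs))
  for (p in 1:2) {
    rows <- integer(0)
    if (n_outer > 0L && length(outer_rows) > 0L) {
      if (length(acs) == 0L) {
        # exact every-R-th line, complementary polarity offset
        rows <- seq.int(p, n_ky, by = round(R))
      } else {
        pos <- (seq_len(n_outer) - 1 + (p - 1) / 2) / n_outer
        rows <- outer_rows[pmin(length(outer_rows),
                                floor(pos * length(outer_rows)) + 1L)]
      }
    }
    mask[unique(c(acs, rows)), , p] <- 1
  }
  new_sampling_pattern(mask, n_acs, R, "uniform", NA_integer_)
}

vd_density <- function(n_ky, power) {
  u <- abs(seq_len(n_ky) - (n_ky + 1) / 2) / (n_ky / 2)
  (pmax(0, 1 - u))^power + 0.01
}

#' Variable-density random ky undersampling
#'
#' ky lines are drawn without replacement from a centered polynomial density
#' `(1 - |ky|/(Nky/2))^density_power`, identical across echoes within each
#' polarity, with disjoint polarity line sets where the budget permits.
#' Deterministic given `seed`.
#'
#' @inheritParams make_uniform
#' @param density_power exponent of the centered density (0 = flat).
#' @param seed integer seed.
#' @export
make_vd <- function(n_ky, n_echoes, R, n_acs = 0L, density_power = 2, seed = 0L) {
  stopifnot(R >= 1, R <= n_ky, density_power >= 0)
  budget <- lines_per_echo(n_ky, R)
  acs <- acs_rows(n_ky, n_acs)
  n_outer <- max(0L, budget - length(acs))
  with_local_seed(seed, {
    mask <- array(0, c(n_ky, n_echoes, 2L))
    dens <- vd_density(n_ky, density_power)
    avail <- setdiff(seq_len(n_ky), acs)
    for (p in 1:2) {
      rows <- integer(0)
      if (n_outer > 0L && length(avail) > 0L) {
        take <- min(n_outer, length(avail))
        rows <- sample(avail, take, prob = dens[avail])
        avail <- setdiff(avail, rows)   # polarity complementarity
        if (length(avail) < n_outer) {
          avail <- setdiff(seq_len(n_ky), acs)  # densities no longer permit
        }
      }
      mask[unique(c(acs, rows)), , p] <- 1
    }
    new_sampling_pattern(mask, n_acs, R, "vd", seed)
  })
}

#' Incoherent ky-TE undersampling from bounded-jump readout trajectories
#'
#' Each fast-spin-echo excitation contributes one ky trajectory across the
#' `n_echoes` gradient echoes, with consecutive echoes constrained to
#' `|ky(j+1) - ky(j)| <= max_jump` lines (a per-readout-train physical
#' constraint on the phase-encode blips). Odd echo entries of every trajectory
#' populate the standard (positive) polarity mask and even entries the flipped
#' (negative) one, so the per-echo ky sets differ across echoes and the
#' aliasing is spread over the ky-TE plane. Starting lines are drawn from the
#' variable-density law. Deterministic given `seed`.
#'
#' @inheritParams make_vd
#' @param max_jump largest allowed ky change (in units of the line spacing)
#'   between adjacent echoes of one excitation; default 12.
#' @export
make_incoherent_kyte <- function(n_ky, n_echoes, R, n_acs = 0L, max_jump = 12,
                                 density_power = 2, seed = 0L) {
  stopifnot(R >= 1, R <= n_ky, max_jump >= 0)
  if (R == 1) {
    mask <- array(1, c(n_ky, n_echoes, 2L))
    return(new_sampling_pattern(mask, n_acs, R, "incoherent_kyte", seed,
                                max_jump = max_jump))
  }
  if (max_jump == 0 && R > 1) stop("max_jump = 0 cannot realize R > 1 incoherent sampling")
  acs <- acs_rows(n_ky, n_acs)
  n_traj <- max(0L, round(2 * n_ky / R) - 2L * length(acs))
  with_local_seed(seed, {
    mask <- array(0, c(n_ky, n_echoes, 2L))
    mask[acs, , ] <- 1
    dens <- vd_density(n_ky, density_power)
    traj <- matrix(NA_integer_, n_traj, n_echoes)
    for (i in seq_len(n_traj)) {
      for (attempt in 1:25) {
        ky <- integer(n_echoes)
        ky[1] <- sample.int(n_ky, 1L, prob = dens)
        for (j in seq_len(n_echoes - 1L)) {
          lo <- max(1L, ky[j] - max_jump); hi <- min(n_ky, ky[j] + max_jump)
          win <- lo:hi
          ky[j + 1L] <- if (length(win) == 1L) win else
            sample(win, 1L, prob = dens[win])
        }
        pol <- ifelse(seq_len(n_echoes) %% 2L == 1L, 1L, 2L)
        fresh <- mask[cbind(ky, seq_len(n_echoes), pol)] == 0
        if (mean(fresh) >= 0.5 || attempt == 25L) {
          mask[cbind(ky, seq_len(n_echoes), pol)] <- 1
          traj[i, ] <- ky
          break
        }
      }
    }
    new_sampling_pattern(mask, n_acs, R, "incoherent_kyte", seed,
                         trajectories = traj, max_jump = max_jump)
  })
}

#' Check the bounded-jump trajectory constraint
#'
#' Exhaustively verifies `|ky(j+1) - ky(j)| <= max_jump` for every excitation
#' of an incoherent ky-TE pattern.
#'
#' @param pattern a `sampling_pattern` of kind `incoherent_kyte`.
#' @return TRUE if every trajectory satisfies the constraint.
#' @export
check_trajectories <- function(pattern) {
  if (is.null(pattern$trajectories)) return(TRUE)
  jumps <- abs(t(apply(pattern$trajectories, 1L, diff)))
  all(jumps <= pattern$max_jump)
}

#' Per-echo and species-domain point-spread functions of a pattern
#'
#' The per-echo PSF is the inverse DFT of each per-echo, per-polarity ky mask.
#' The species-domain PSF passes a centered water delta through the joint
#' normal operator E^H E built with single identity coil sensitivities, zero
#' field and zero shifts, so only the ky-TE sampling footprint shapes it.
#'
#' @param pattern a `sampling_pattern`.
#' @param nx readout size used for the species-domain PSF (default `n_ky`).
#' @param mainlobe_radius pixels around the mainlobe excluded from the
#'   species-domain sidelobe search (mainlobe width is set by the sampling
#'   density profile, not by aliasing).
#' @return list with `per_echo` (`[Nky, Nt, 2]` complex PSFs),
#'   `per_echo_sidelobe` (max |sidelobe|/|mainlobe| over echoes/polarities),
#'   `species` (`[nx, Nky, 3]` water-delta response) and `species_sidelobe`.
#' @export
psf <- function(pattern, nx = pattern$n_ky, mainlobe_radius = 3L) {
  nky <- pattern$n_ky; nt <- pattern$n_echoes
  per <- array(0i, c(nky, nt, 2L))
  side <- 0
  for (p in 1:2) for (j in seq_len(nt)) {
    v <- stats::fft(pattern$mask[, j, p], inverse = TRUE) / nky
    per[, j, p] <- v
    if (Mod(v[1]) > 0) {
      s <- max(Mod(v[-1])) / Mod(v[1])
      side <- max(side, s)
    }
  }
  # species-domain PSF through the shared normal operator
  model <- spectral_model()
  times <- echo_times(nt)
  field <- field_params(matrix(0, nx, nky))
  sens <- polarity_sens(array(1 + 0i, c(nx, nky, 1L)),
                        array(1 + 0i, c(nx, nky, 1L)), method = "identity")
  E <- build_joint_operator(field, sens, pattern, times, model,
                            shift_set_manual(0, 0))
  delta <- matrix(0i, nx, nky)
  ctr <- c(nx %/% 2L + 1L, nky %/% 2L + 1L)
  delta[ctr[1], ctr[2]] <- 1
  zero <- matrix(0i, nx, nky)
  resp <- E$adjoint(E$forward(species_images(delta, zero, zero)))
  spc <- array(0i, c(nx, nky, 3L))
  spc[, , 1] <- resp$w; spc[, , 2] <- resp$f; spc[, , 3] <- resp$s
  main <- Mod(spc[ctr[1], ctr[2], 1])
  mags <- Mod(spc)
  r <- mainlobe_radius
  mags[pmax(1, ctr[1] - r):pmin(nx, ctr[1] + r),
       pmax(1, ctr[2] - r):pmin(nky, ctr[2] + r), ] <- 0
  list(per_echo = per, per_echo_sidelobe = side,
       species = spc, species_sidelobe = max(mags) / main)
}
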