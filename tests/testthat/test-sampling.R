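# ky-TE undersampling pattern design and PSF analysis.

test_that("uniform patterns count lines correctly", {
  expect_true(all(make_uniform(16L, 3L, 1, 0L)$mask == 1))
  p <- make_uniform(8L, 3L, 2, 0L)
  expect_equal(sum(p$mask[, 1, 1]), 4)
  expect_equal(sum(p$mask[, 1, 2]), 4)
  # complementary polarity offset
  expect_equal(which(p$mask[, 1, 1] == 1) + 1L, which(p$mask[, 1, 2] == 1))
  # same lines at every echo within a polarity
  expect_true(all(p$mask[, 1, 1] == p$mask[, 3, 1]))
  p6 <- make_uniform(360L, 7L, 6, 32L)
  expect_gte(p6$R_achieved, 5.4)
  expect_lte(p6$R_achieved, 6.6)
  expect_error(make_uniform(8L, 3L, 10, 0L))
})

test_that("ACS block is fully sampled and masks are binary", {
  for (p in list(make_uniform(64L, 7L, 4, 16L),
                 make_vd(64L, 7L, 4, 16L, seed = 1L),
                 make_incoherent_kyte(64L, 7L, 4, 8L, seed = 1L))) {
    acs <- wfsrecon:::acs_rows(64L, p$n_acs)
    expect_true(all(p$mask[acs, , ] == 1))
    expect_true(all(p$mask %in% c(0, 1)))
    expect_true(is.finite(p$R_achieved))
  }
})

test_that("variable-density sampling is seeded and center-weighted", {
  p1 <- make_vd(96L, 7L, 4, 12L, seed = 3L)
  p2 <- make_vd(96L, 7L, 4, 12L, seed = 3L)
  expect_identical(p1$mask, p2$mask)
  # same lines across echoes within polarity
  expect_true(all(p1$mask[, 1, 1] == p1$mask[, 5, 1]))
  # sampled-line density decreases with |ky| in expectation
  cnt <- rep(0, 96)
  for (s in seq_len(50)) {
    cnt <- cnt + make_vd(96L, 7L, 4, 0L, seed = s)$mask[, 1, 1]
  }
  bins <- split(cnt, cut(abs(seq_len(96) - 48.5), 4))
  expect_true(all(diff(vapply(bins, mean, numeric(1))) <= 0))
})

test_that("incoherent ky-TE trajectories respect the bounded-jump constraint", {
  p <- make_incoherent_kyte(128L, 7L, 6, 12L, max_jump = 12, seed = 0L)
  expect_true(check_trajectories(p))
  jumps <- abs(t(apply(p$trajectories, 1L, diff)))
  expect_lte(max(jumps), 12)
  # odd echoes populate the standard mask, even the flipped (outside ACS)
  acs <- wfsrecon:::acs_rows(128L, p$n_acs)
  expect_equal(sum(p$mask[-acs, c(2, 4, 6), 1]), 0)
  expect_equal(sum(p$mask[-acs, c(1, 3, 5, 7), 2]), 0)
  # per-echo sampled sets distinct for at least ceil(Nt/2) adjacent pairs
  sets <- lapply(seq_len(7L), function(j)
    which(p$mask[, j, 1] == 1 | p$mask[, j, 2] == 1))
  distinct <- sum(vapply(seq_len(6L), function(j)
    !identical(sets[[j]], sets[[j + 1]]), logical(1)))
  expect_gte(distinct, 4L)
  # R = 1 with unbounded jumps keeps everything
  expect_true(all(make_incoherent_kyte(32L, 7L, 1, 0L, max_jump = Inf)$mask == 1))
  expect_error(make_incoherent_kyte(32L, 7L, 2, 0L, max_jump = 0))
  expect_identical(p$mask,
                   make_incoherent_kyte(128L, 7L, 6, 12L, seed = 0L)$mask)
})

test_that("per-echo PSF of a fully sampled pattern is a delta", {
  ps <- psf(make_uniform(64L, 7L, 1, 0L), nx = 64L)
  expect_equal(ps$per_echo_sidelobe, 0)
  expect_equal(ps$species_sidelobe, 0, tolerance = 1e-10)
})

test_that("uniform R=6 per-echo PSF has exactly 5 equal coherent ghosts", {
  p <- make_uniform(120L, 7L, 6, 0L)
  ps <- psf(p, nx = 120L)
  v <- Mod(ps$per_echo[, 1, 1])
  peaks <- which(v > 0.5 * max(v))
  expect_length(peaks, 6L)            # mainlobe + 5 ghosts
  expect_lt(diff(range(v[peaks])) / max(v), 1e-12)
  expect_equal(sum(v > 1e-9 * max(v)), 6L)
})

test_that("incoherent ky-TE species PSF beats uniform at R=6", {
  su <- psf(make_uniform(240L, 7L, 6, 0L), nx = 240L)$species_sidelobe
  si <- psf(make_incoherent_kyte(240L, 7L, 6, 0L, seed = 0L),
            nx = 240L)$species_sidelobe
  expect_lt(si, su)
})
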