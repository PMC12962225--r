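# Chemical-shift encoding physics: phasors, encoding matrix, forward map and
# least-squares separation.

test_that("fat model constants are normalized and phasors behave", {
  model <- fix_model()
  expect_equal(sum(model$fat_amp), 1, tolerance = 1e-13)
  expect_equal(model$n_fat, 9L)
  expect_equal(fat_phasor(0, model), 1 + 0i)
  expect_equal(silicone_phasor(0, model), 1 + 0i)
  ts <- seq(-5e-3, 5e-3, length.out = 101)
  expect_true(all(Mod(fat_phasor(ts, model)) <= 1 + 1e-12))
  # full silicone period returns to 1
  fs <- silicone_freq_hz(model)
  expect_equal(silicone_phasor(1 / abs(fs), model), 1 + 0i, tolerance = 1e-10)
  expect_error(fat_phasor(NaN, model))
})

test_that("ppm-to-Hz conversion matches hand computation", {
  model <- fix_model()
  # -4.9 ppm at 127.7 MHz
  expect_equal(silicone_freq_hz(model), -625.73, tolerance = 1e-8)
  sm1 <- spectral_model(fat_ppm = -3.4, fat_amp = 1)
  # -3.4e-6 * 127.7e6 = -434.18 Hz
  expect_equal(fat_freqs_hz(sm1), -434.18, tolerance = 1e-8)
  expect_equal(fat_phasor(1e-3, sm1), exp(2i * pi * (-434.18) * 1e-3),
               tolerance = 1e-12)
})

test_that("encoding matrix has the expected structure and rank", {
  model <- fix_model()
  times <- fix_times()
  A0 <- encoding_matrix(0 + 0i, times, model)
  expect_equal(A0[, 1], rep(1 + 0i, times$n))
  # water column decays monotonically for pure decay, t >= 0
  Ad <- encoding_matrix(-30 + 0i, times, model)
  wpos <- Mod(Ad[times$t >= 0, 1])
  expect_true(all(diff(wpos) < 0))
  # full rank across the field range
  for (fB in seq(-200, 200, by = 25)) {
    A <- encoding_matrix(2i * pi * fB, times, model)
    d <- svd(A)$d
    expect_equal(sum(d >= 1e-8 * d[1]), 3L)
  }
})

test_that("forward map is linear and matches the dense per-pixel oracle", {
  model <- fix_model()
  times <- fix_times()
  n <- 8L
  r1 <- rand_species(n, 21L)
  r2 <- rand_species(n, 22L)
  field <- wfsrecon:::with_local_seed(23L, field_params(
    matrix(stats::rnorm(n * n, 0, 80), n, n),
    matrix(stats::runif(n * n, 0, 50), n, n)))
  F1 <- forward_species(r1, field, times, model)
  F2 <- forward_species(r2, field, times, model)
  comb <- species_images(2 * r1$w - 3i * r2$w, 2 * r1$f - 3i * r2$f,
                         2 * r1$s - 3i * r2$s)
  expect_lt(wfsrecon:::nrmse(forward_species(comb, field, times, model),
                             2 * F1 - 3i * F2), 1e-12)
  # dense oracle
  for (px in list(c(1L, 1L), c(3L, 7L), c(8L, 2L))) {
    A <- encoding_matrix(field$mu[px[1], px[2]], times, model)
    ref <- A %*% c(r1$w[px[1], px[2]], r1$f[px[1], px[2]], r1$s[px[1], px[2]])
    expect_equal(F1[px[1], px[2], ], as.vector(ref), tolerance = 1e-12)
  }
})

test_that("separation inverts the forward map with exact field", {
  model <- fix_model()
  times <- fix_times()
  n <- 12L
  rho <- rand_species(n, 31L)
  field <- wfsrecon:::with_local_seed(32L, field_params(
    matrix(stats::rnorm(n * n, 0, 100), n, n),
    matrix(stats::runif(n * n, 0, 60), n, n)))
  ech <- forward_species(rho, field, times, model)
  back <- lsq_separate(ech, field, times, model)
  expect_lt(species_nrmse(back, rho), 1e-9)
  # zero in, zero out
  z <- species_images(matrix(0i, n, n), matrix(0i, n, n), matrix(0i, n, n))
  ze <- lsq_separate(forward_species(z, field, times, model), field, times, model)
  expect_equal(max(Mod(ze$w), Mod(ze$f), Mod(ze$s)), 0)
  # noise-only input stays finite
  noisy <- wfsrecon:::with_local_seed(33L, wfsrecon:::crandn(c(n, n, times$n)))
  out <- lsq_separate(noisy, field, times, model)
  expect_true(all(is.finite(Mod(out$w)), is.finite(Mod(out$f)),
                  is.finite(Mod(out$s))))
})

test_that("spectral model loads from the constants file and validates", {
  def <- wfsrecon:::load_fat_model()
  expect_length(def$ppm, 9L)
  m <- spectral_model(fat_ppm = def$ppm, fat_amp = def$amp)
  expect_equal(sum(m$fat_amp), 1, tolerance = 1e-13)
  expect_error(spectral_model(fat_ppm = c(1, 2), fat_amp = c(1)))
  expect_error(echo_times(0))
  expect_error(field_params(matrix(1, 2, 2), matrix(-1, 2, 2)))
})
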