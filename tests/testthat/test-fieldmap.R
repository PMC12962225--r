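# Discrete VARPRO field mapping and R2' estimation.

test_that("varpro residual vanishes at the true field and is multimodal", {
  model <- fix_model()
  times <- fix_times()
  rho <- species_images(matrix(0.7 + 0i, 1, 1), matrix(0.3 + 0i, 1, 1),
                        matrix(0 + 0i, 1, 1))
  px <- forward_species(rho, field_params(matrix(73, 1, 1)), times, model)[1, 1, ]
  expect_lt(varpro_residual(px, 73, times, model), 1e-18)
  sweep <- vapply(seq(-600, 600, by = 2), function(f)
    varpro_residual(px, f, times, model), numeric(1))
  n_min <- sum(diff(sign(diff(sweep))) > 0)
  expect_gte(n_min, 2L)
  # invariant to a global complex scale
  r1 <- varpro_residual(px * (2 - 1i), 10, times, model)
  expect_equal(r1, Mod(2 - 1i)^2 * varpro_residual(px, 10, times, model),
               tolerance = 1e-10)
  # pure noise stays finite
  noise <- wfsrecon:::with_local_seed(4L, wfsrecon:::crandn(7))
  expect_true(is.finite(varpro_residual(noise, 0, times, model)))
})

test_that("smooth field maps are recovered to within the grid spacing", {
  model <- fix_model()
  times <- fix_times()
  ph <- make_phantom(phantom_config(shape = c(48L, 48L), n_coils = 3L,
                                    fB_amplitude = 120, seed = 5L))
  ech <- forward_species(ph$truth, ph$field, times, model)
  cands <- field_candidates(f_max = 300, delta_f = 2)
  fest <- estimate_fieldmap(ech, cands, times, model)
  err <- (fest$fB - ph$field$fB)[ph$support]
  expect_lt(sqrt(mean(err^2)), cands$delta_f)
})

test_that("a constant field map is recovered almost exactly", {
  model <- fix_model()
  times <- fix_times()
  n <- 24L
  rho <- species_images(matrix(0.8 + 0i, n, n), matrix(0.4 + 0i, n, n),
                        matrix(0i, n, n))
  truth <- field_params(matrix(37, n, n))
  ech <- forward_species(rho, truth, times, model)
  fest <- estimate_fieldmap(ech, field_candidates(100, 2), times, model)
  expect_lt(max(abs(fest$fB - 37)), 0.5)
})

test_that("R2-prime is recovered and clipped to its range", {
  model <- fix_model()
  times <- fix_times()
  ph <- make_phantom(phantom_config(shape = c(48L, 48L), n_coils = 3L,
                                    r2p_range = c(30, 30), seed = 6L))
  ech <- forward_species(ph$truth, ph$field, times, model)
  f0 <- estimate_fieldmap(ech, field_candidates(200, 2), times, model)
  fest <- estimate_r2prime(ech, f0, times, model)
  expect_lt(max(abs(fest$r2p[ph$support] - 30)), 0.5)
  # r2p truth 0
  ph0 <- make_phantom(phantom_config(shape = c(32L, 32L), n_coils = 2L,
                                     r2p_range = c(0, 0), seed = 6L))
  e0 <- forward_species(ph0$truth, ph0$field, times, model)
  fe0 <- estimate_r2prime(e0, field_params(ph0$field$fB, 0), times, model)
  expect_lte(max(fe0$r2p[ph0$support]), 1)
  # noise only: finite, clipped
  noise <- wfsrecon:::with_local_seed(9L, wfsrecon:::crandn(c(16, 16, 7)))
  fn <- estimate_r2prime(noise, field_params(matrix(0, 16, 16)), times, model)
  expect_true(all(fn$r2p >= 0 & fn$r2p <= 100))
})

test_that("water-silicone swaps are prevented inside the implant", {
  model <- fix_model()
  times <- fix_times()
  ph <- make_phantom(phantom_config(shape = c(48L, 48L), n_coils = 3L, seed = 6L))
  ech <- forward_species(ph$truth, ph$field, times, model)
  fest <- estimate_fieldmap(ech, field_candidates(200, 2), times, model)
  fest <- estimate_r2prime(ech, fest, times, model)
  sep <- lsq_separate(ech, fest, times, model)
  ip <- ph$roi_implant
  en_s <- sum(Mod(sep$s[ip])^2)
  en_tot <- en_s + sum(Mod(sep$w[ip])^2) + sum(Mod(sep$f[ip])^2)
  expect_gte(en_s / en_tot, 0.9)
})

test_that("a too-narrow candidate grid triggers the edge warning", {
  model <- fix_model()
  times <- fix_times()
  n <- 16L
  rho <- species_images(matrix(1 + 0i, n, n), matrix(0i, n, n), matrix(0i, n, n))
  ech <- forward_species(rho, field_params(matrix(90, n, n)), times, model)
  expect_warning(estimate_fieldmap(ech, field_candidates(50, 2), times, model),
                 "grid edge")
})
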