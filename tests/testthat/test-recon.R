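# Joint and two-stage reconstructions.

test_that("noiseless fully sampled data is recovered exactly by both methods", {
  model <- fix_model()
  times <- fix_times()
  ph <- make_phantom(phantom_config(shape = c(48L, 48L), n_coils = 3L, seed = 12L))
  pat <- make_uniform(48L, times$n, 1, 0L)
  sh <- shift_set_manual(0, 0)
  kd <- simulate_kspace(ph, pat, times, model, sh, noise_sigma = 0)
  sens <- true_polarity_sens(ph)
  E <- build_joint_operator(ph$field, sens, pat, times, model, sh)
  rec <- joint_recon(kd$y, E, recon_config(max_iter = 80L, tol = 1e-12,
                                           adaptive_threshold = FALSE))
  expect_lt(species_nrmse(rec, ph$truth), 1e-3)
  conv <- attr(rec, "convergence")
  expect_true(all(diff(conv$objective[-(1:5)]) <=
                    1e-9 * max(conv$objective[1], 1)))
  rec2 <- two_stage_recon(kd, sens, cfg = recon_config(max_iter = 60L,
                                                       tol = 1e-12),
                          field = ph$field, model = model)
  expect_lt(species_nrmse(rec2, ph$truth), 1e-3)
})

test_that("zero data with positive lambda reconstructs to zero", {
  model <- fix_model()
  times <- fix_times()
  ph <- fix_phantom_small()
  pat <- make_uniform(32L, times$n, 2, 8L)
  E <- build_joint_operator(ph$field, true_polarity_sens(ph), pat, times,
                            model, shift_set(model))
  y0 <- array(0i, c(32L, 32L, 3L, times$n, 2L))
  rec <- joint_recon(y0, E, recon_config(lambda_w = 0.1, lambda_f = 0.1,
                                         lambda_s = 0.1, max_iter = 10L))
  expect_equal(max(Mod(rec$w), Mod(rec$f), Mod(rec$s)), 0)
})

test_that("stage-1 per-echo reconstruction only sees its own echo's data", {
  model <- fix_model()
  times <- fix_times()
  ph <- fix_phantom_small()
  pat <- make_incoherent_kyte(32L, times$n, 3, 8L, seed = 5L)
  kd <- simulate_kspace(ph, pat, times, model, shift_set_manual(0, 0),
                        noise_sigma = 0)
  sens <- true_polarity_sens(ph)
  cfg <- recon_config(lambda_echo = 1e-3, max_iter = 15L)
  r1 <- two_stage_recon(kd, sens, cfg = cfg, field = ph$field, model = model)
  # corrupt every echo except echo 3: echo 3's stage-1 image is unchanged
  kd2 <- kd
  kd2$y[, , , -3L, ] <- kd2$y[, , , -3L, ] * 7
  r2 <- two_stage_recon(kd2, sens, cfg = cfg, field = ph$field, model = model)
  expect_equal(attr(r1, "echoes")[, , 3], attr(r2, "echoes")[, , 3])
  expect_false(isTRUE(all.equal(attr(r1, "echoes")[, , 2],
                                attr(r2, "echoes")[, , 2])))
})

test_that("per-echo sampling is sparser than the joint aggregate at R=6", {
  pat <- make_incoherent_kyte(128L, 7L, 6, 12L, seed = 0L)
  per_echo <- colSums(pat$mask[, , 1] + pat$mask[, , 2])
  total <- sum(pat$mask)
  # stage 1 sees one echo's lines; the joint solve sees all echoes
  expect_true(all(per_echo < total))
  expect_gte(2 * 128 / min(per_echo), 128 * 7 * 2 / total)
})

test_that("the lambda grid search is exhaustive and favors no regularization
           on clean data", {
  model <- fix_model()
  times <- fix_times()
  ph <- fix_phantom_small()
  pat <- make_uniform(32L, times$n, 1, 0L)
  sh <- shift_set_manual(0, 0)
  kd <- simulate_kspace(ph, pat, times, model, sh, noise_sigma = 0)
  E <- build_joint_operator(ph$field, true_polarity_sens(ph), pat, times,
                            model, sh)
  cfg <- recon_config(max_iter = 40L)
  one <- grid_search_lambdas(kd$y, E, cfg, 1e-3, 1e-3, 1e-3, ph$truth)
  expect_equal(unname(one$best), c(1e-3, 1e-3, 1e-3))
  expect_equal(nrow(one$table), 1L)
  gs <- grid_search_lambdas(kd$y, E, cfg, c(0, 0.5), c(0, 0.5), c(0, 0.5),
                            ph$truth)
  expect_equal(nrow(gs$table), 8L)
  expect_equal(unname(gs$best), c(0, 0, 0))
})

test_that("disabling the shift operator misplaces off-resonant species edges", {
  model <- fix_model()
  times <- fix_times()
  ph <- make_phantom(phantom_config(shape = c(48L, 48L), n_coils = 3L, seed = 13L))
  pat <- make_uniform(48L, times$n, 1, 0L)
  sh <- shift_set_manual(2.5, 4)   # exaggerated displacements
  kd <- simulate_kspace(ph, pat, times, model, sh, noise_sigma = 0)
  sens <- true_polarity_sens(ph)
  cfg <- recon_config(max_iter = 60L, adaptive_threshold = FALSE)
  E_on <- build_joint_operator(ph$field, sens, pat, times, model, sh)
  E_off <- build_joint_operator(ph$field, sens, pat, times, model,
                                shift_set_manual(0, 0))
  rec_on <- joint_recon(kd$y, E_on, cfg)
  rec_off <- joint_recon(kd$y, E_off, cfg)
  # readout profile through the implant: the half-max edge of the silicone
  # disc must sit within half a pixel with the model, and move by >= dx/2
  # without it (the two polarities smear the disc in opposite directions)
  ky <- round(mean(col(ph$roi_implant)[ph$roi_implant]))
  edge <- function(img) {
    prof <- Mod(img[, ky])
    range(which(prof > 0.5 * max(prof)))
  }
  e_truth <- edge(ph$truth$s)
  e_on <- edge(rec_on$s)
  e_off <- edge(rec_off$s)
  expect_lte(max(abs(e_on - e_truth)), 1)
  expect_gte(max(abs(e_off - e_truth)), 4 / 2)
  expect_gt(wfsrecon:::nrmse(rec_off$s, ph$truth$s),
            5 * wfsrecon:::nrmse(rec_on$s, ph$truth$s))
})
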