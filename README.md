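# wfsrecon

Water–fat–silicone (WFS) MRI simulation and reconstruction in R.

MRI of patients with silicone breast implants needs water-, fat- and
silicone-specific images from a single T2-weighted acquisition. Silicone
resonates at −4.9 ppm relative to water, close to the bulk fat resonance near
−3.4 ppm, so frequency-selective suppression is fragile; chemical-shift
encoding instead acquires several bipolar gradient echoes around each fast
spin echo and separates the species from their phase evolution. `wfsrecon`
implements that processing chain end to end on synthetic data:

* a digital phantom (mixed water/fat tissue, pure-silicone implant, smooth
  field and R2′ maps, coil sensitivities, bipolar Nyquist-ghost phase) and a
  k-space simulator that shares its forward operator with the reconstruction;
* ky–TE undersampling design: uniform, variable-density and incoherent
  trajectory-based patterns with a ≤12Δk inter-echo jump constraint, ACS
  bookkeeping and point-spread-function analysis;
* Nyquist ghost correction by stacking the two readout polarities along the
  coil dimension (ESPIRiT calibration + SENSE-like combination);
* discrete VARPRO-style field mapping with spatial smoothness and a
  vectorized R2′ fit;
* two reconstructions: the **two-stage** baseline (per-echo wavelet-L1
  compressed sensing, then separation) and the **joint** species-domain
  compressed-sensing reconstruction

  ρ̂ = argmin‖D±FS±A(μ̂)M±ρ − y±‖² + λw‖ρw‖₁ + λf‖Wρf‖₁ + λs‖Wρs‖₁,

  solved by FISTA with adaptive restart and species-adaptive
  soft-thresholding, with chemical-shift displacement operators M± that
  model the opposing fat/silicone shifts of bipolar readouts;
* evaluation: SSIM, PSNR, GMSD and the SWFS / WS / FS species-leakage
  percentages, plus end-to-end experiment drivers.

## Worked example

```r
library(wfsrecon)

model <- spectral_model()        # nine-peak fat, silicone at -4.9 ppm, 3 T
times <- echo_times()            # 7 echoes, +/-3 ms around the spin echo
ph    <- make_phantom(phantom_config(shape = c(96, 96), n_coils = 6, seed = 1))

# incoherent ky-TE pattern at R = 6 with a 12-line ACS block
pat <- make_incoherent_kyte(96, times$n, R = 6, n_acs = 12, seed = 0)
kd  <- simulate_kspace(ph, pat, times, model, noise_sigma = 2e-4)

# calibration, field mapping, joint reconstruction
sens  <- estimate_polarity_sensitivities(kd)
field <- estimate_field_from_acs(kd, sens, times, model)
E     <- build_joint_operator(field, sens, pat, times, model, shift_set(model))
rec   <- joint_recon(kd$y, E, recon_config(lambda_w = 0.05, lambda_f = 0.05,
                                           lambda_s = 0.05, max_iter = 80))

ssim(Mod(rec$s), Mod(ph$truth$s))
#> [1] 0.8126651
leakage_swfs(rec$s, ph$roi_tissue, ph$roi_implant)
#> [1] 0.9468467
```

The sixfold-undersampled silicone image reaches SSIM 0.81 against ground
truth, and the water/fat leakage onto it (SWFS) is below 1% — the silicone
image stays clean on the tissue side, which is the clinically relevant
property. `run_retrospective_comparison()` reproduces the full
comparison (uniform / variable-density / incoherent sampling × two-stage /
joint reconstruction, λ tuned by grid search) and writes a CSV table;
`run_demo()` produces the seven output contrasts W, F, S, W+F, F+S, W+S,
W+F+S as NIfTI volumes. A thin command-line front end lives in
`inst/cli/wfs.R` (`Rscript wfs.R compare --out outdir`, `... demo`, etc.).

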