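---
title: "Water-fat-silicone imaging with wfsrecon: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-fat-silicone imaging with wfsrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MRI of patients with silicone breast implants needs three chemically distinct
species resolved from one acquisition: water, fat, and silicone. Silicone
resonates at -4.9 ppm relative to water, uncomfortably close to the bulk fat
resonance near -3.4 ppm, which makes frequency-selective suppression fragile.
Chemical-shift encoding instead samples several gradient echoes around each
spin echo of a fast-spin-echo (FSE) train and separates the species from their
distinct phase evolution. `wfsrecon` implements a complete, self-contained
simulation and reconstruction chain for this problem: a digital phantom with a
silicone implant, a bipolar multi-echo k-space simulator, incoherent ky-TE
undersampling design, Nyquist ghost correction by polarity stacking,
field-map and R2' estimation, and two reconstruction methods (two-stage and
joint species-domain compressed sensing) with quantitative evaluation.

## Signal model

At gradient-echo time $t_j$ (seconds, signed relative to the spin echo), the
pixel signal is

$$x(t_j) = e^{\mu t_j}\left(\rho_w + \Phi_f(t_j)\,\rho_f +
\Phi_s(t_j)\,\rho_s\right),\qquad \mu = 2\pi i f_B - R_2',$$

with complex species densities $\rho_w,\rho_f,\rho_s$, off-resonance $f_B$
(Hz), effective reversible decay $R_2'$ (1/s), the nine-peak fat phasor
$\Phi_f(t)=\sum_p \alpha_p e^{2\pi i f_{f,p} t}$ ($\sum\alpha_p = 1$) and the
single-peak silicone phasor $\Phi_s(t)=e^{2\pi i f_s t}$. Echo times default
to $t = (-3,\dots,3)\cdot 1.0$ ms (configurable to 1.06 ms spacing for
ramp-sampled readouts). The model is applied literally with signed $t$: the
$R_2'$ term amplifies pre-spin-echo samples rather than using $|t|$; the
simulator and the reconstruction operator share the identical convention, so
the chain is model-matched by construction. Spin-spin ($T_2$) decay along the
FSE train is an acquisition property (it sets image contrast, here emulated
through the ground-truth magnitudes) and is not part of the per-spin-echo
model.

The nine-peak fat table ships in a versioned YAML constants file
(`inst/extdata/fat_model_9peak.yaml`). The package treats it as substitutable
calibration data: amplitudes are renormalized on load and any published
nine-peak model can replace it.

## Bipolar acquisition, ghosting and displacement

Bipolar readouts alternate gradient polarity between adjacent echoes. Two
consequences are modeled:

* **Nyquist ghost phase.** Eddy currents and gradient delays give the two
  polarities a smooth relative phase (modeled as
  $c_0 + c_1 x + c_2 x^2$ across the readout FOV). The simulator splits it
  symmetrically ($e^{\pm i\phi/2}$); only the difference is identifiable, and
  the symmetric split leaves the standard polarity unbiased.
* **Opposing chemical-shift displacement.** Off-resonant species displace
  along the readout by $\Delta x = f/\mathrm{BW_{pixel}}$ with opposite signs
  for the two polarities. Fat uses its amplitude-weighted mean frequency as a
  single bulk shift. The displacement operator `shift_operator()` is a unitary
  Fourier-domain subpixel shift, so its adjoint is exact.

The joint forward operator is the composition (right to left)

$$E = D_\pm\, F\, S_\pm\, A(\hat\mu)\, M_\pm,$$

per-species shift, chemical encoding, polarity-resolved coil/ghost
sensitivities, unitary 2D DFT, and the ky sampling masks. All factors have
exact adjoints, so $E$ passes adjoint dot-product tests at machine precision,
and `simulate_kspace()` calls this same operator — the simulator is never a
separate implementation of the physics.

## Sampling design

Patterns are binary $N_{ky}\times N_t\times 2$ masks with a fully sampled
central ACS block (both polarities, all echoes). Acceleration is accounted on
the combined two-polarity data and *includes* the ACS block in the per-echo
line budget, so the achieved and nominal R agree; with no ACS the uniform
pattern reduces to exact every-R-th-line sampling with complementary polarity
offsets.

The incoherent ky-TE design is trajectory-based: each FSE excitation
contributes one ky value per echo, with $|k_y(j{+}1)-k_y(j)|\le 12\,\Delta k$
(a physical constraint on the inter-echo phase-encode blips), starting points
drawn from a centered polynomial variable density (exponent 2 by default; the
density law is a free parameter), odd echo entries assigned to the standard
polarity and even entries to the flipped one. `psf()` quantifies the designs:
uniform sampling concentrates aliasing into R-1 coherent ghosts, while the
incoherent design spreads it into a low pseudo-noise floor. The species-domain
PSF passes a water delta through $E^{\mathsf H}E$ with identity coils and zero
field so only the sampling footprint acts; pixels within 3 pixels of the
mainlobe are excluded from the sidelobe statistic because the mainlobe width
reflects the density profile, not aliasing, and PSF comparisons are run
without ACS since the common fully sampled center contributes an identical
low-pass skirt to every design.

## Calibration and ghost correction

Stacking positive- and negative-polarity ACS data along the coil dimension
turns the ghost phase into part of a $2N_c$-channel sensitivity set.
`estimate_polarity_sensitivities()` runs ESPIRiT on the stacked channels:
block-Hankel calibration matrix (6x6 kernels), SVD threshold $0.02\,\sigma_1$,
per-pixel eigendecomposition of the image-domain kernel Gram operator,
dominant eigenvector kept where the eigenvalue exceeds 0.9, phases referenced
to the first positive-readout channel. These are standard published defaults,
kept as tunable arguments. A cheaper `acs_phase_diff` method (low-resolution
polarity images against reference coil maps, smoothed phase difference split
in half) is retained as a cross-check. `ngc_sense()` then solves the stacked
SENSE normal equations per echo by conjugate gradients, which removes the
ghost whenever the aggregate sampling has full rank.

## Field and R2' mapping

`estimate_fieldmap()` minimizes, over a discrete $f_B$ grid (default
$\pm 300$ Hz in 2 Hz steps), the VARPRO residual — the echo-vector energy
orthogonal to the column space of $A(2\pi i f_B)$ — plus an L1 spatial
smoothness penalty, using checkerboard iterated conditional modes from three
starts: the per-pixel argmin, its median-filtered version, and the
median-filtered first ICM result. The third start matters because small
(2x2) ambiguity islands are ICM-stable — flipping any single island pixel is
smoothness-neutral — while median filtering the converged labels removes them
outright; the lowest final energy wins, which also supplies the
smoothness-favoring tie-break. A per-pixel
quadratic fit between neighboring grid points refines $f_B$ below the grid
spacing. This is a deliberate single-layer simplification of graph-cut field
mapping: its contract is parameter recovery on smooth maps, not parity with
multi-layer solvers near metal. Signal-free pixels carry no data preference
and simply follow the smoothness term.

`estimate_r2prime()` then fits $R_2'\in[0,100]$ s$^{-1}$ per pixel with
$f_B$ fixed. Because the normal-equation Gram matrix depends on $R_2'$ only,
the search vectorizes across all pixels on a 1 s$^{-1}$ grid followed by
per-pixel parabolic refinement; this replaces a per-pixel golden-section loop
at identical accuracy (well below the 0.5 s$^{-1}$ recovery target) and runs
orders of magnitude faster in R.

In the full pipeline (`estimate_field_from_acs()`) the maps are estimated
from Hann-apodized ACS reconstructions and box-smoothed (radius 3 pixels):
the acquisition's field mapping is intrinsically low-resolution, the true
maps are smooth, and at desk-scale ACS widths truncation ringing otherwise
leaks into $R_2'$.

## Reconstruction

**Two-stage.** Each echo image is reconstructed independently by FISTA on the
polarity-stacked data term with a single wavelet-L1 weight, then field mapping
and per-pixel least-squares separation are applied. Chemical-shift
displacement cannot be modeled per species in this formulation.

**Joint.** The species images are estimated directly:

$$\hat\rho = \arg\min_\rho \|E\rho - y\|_2^2 + \lambda_w\|\rho_w\|_1 +
\lambda_f\|W\rho_f\|_1 + \lambda_s\|W\rho_s\|_1,$$

water regularized in the image domain (it is compressible there), fat and
silicone in an orthogonal Daubechies-4 wavelet domain (3 levels, periodic
boundary — orthogonality keeps the proximal step exact; the transform is
hand-written since no wavelet package is part of the dependency set). The
solver is FISTA with adaptive restart: on an objective increase the momentum
is discarded and a plain proximal step from the previous iterate is taken, so
the recorded objective is non-increasing once the adaptive thresholds freeze.
The step is $1/(2L)$ with $L$ from power iteration on $E^{\mathsf H}E$ plus a
2.5% margin. Adaptive soft-thresholding scales each species' threshold by
that species' current 99th-percentile magnitude (robust to hot pixels) so the
much darker silicone/fat channels are not over-penalized; the scales freeze
after 5 iterations so the objective is well defined. TV regularization for
water would also be defensible but is not the default. The $\lambda$ triple
is chosen by exhaustive grid search scored by mean species SSIM against a
reference reconstruction, mirroring a retrospective tuning setting.

## Evaluation

SSIM (11x11 Gaussian window, $\sigma=1.5$, $K_1=0.01$, $K_2=0.03$, border
excluded from pooling), PSNR (capped at 200 dB), and GMSD (Prewitt gradients
after 2x average downsampling, $c=170$ on the 0-255 scale, standard-deviation
pooling) are computed on magnitude images normalized to the reference's 99th
percentile, making all metrics invariant to common positive rescaling.
Species leakage uses ratios of ROI means: silicone signal outside versus
inside the implant (SWFS), and water (WS) or fat (FS) signal inside the
implant relative to silicone there, each times 100%. ROI masks come from the
phantom ground truth, eroded by 2 pixels to avoid edge ringing. Aggregation
over repeated runs reports mean and median.

## What the phantom does and does not emulate

The generator produces piecewise-smooth mixed water/fat tissue with internal
structure, a pure-silicone disc implant, a smooth polynomial-plus-bump field
map (default within ±80 Hz), a smooth R2' map (5-40 1/s), offset-Gaussian
coil magnitudes with smooth phases, the polynomial ghost phase, and complex
Gaussian k-space noise added only to sampled lines. It does not emulate
anatomical geometry, motion, T2 contrast evolution along the FSE train,
ramp-sampling non-Cartesian effects, or model mismatch in the chemical-shift
displacement (simulator and reconstruction share one $\Delta x$ per species
by design). Passing tests therefore demonstrate correctness of the operators
and algorithms under the stated model, and directional algorithmic claims
(joint versus two-stage, incoherent versus uniform sampling), not clinical
image quality.

## Problem sizes and defaults

The desk-scale default geometry is a 96x96 phantom with 6 coils, 7 echoes and
an ACS width of 12 lines (the same ~13% ACS fraction as a 240-line clinical
matrix), chosen so that a full retrospective comparison — calibration, field
mapping, reference reconstruction, and tuned reconstructions for two patterns
times two methods — completes in a few minutes in pure R. Exactness checks
(noiseless $\lambda=0$ inversion against a conjugate-gradient oracle) run at
128x128 with 8 coils. At these sizes an R=6 pattern keeps only ~32 combined
lines per echo, so absolute quality metrics are far below what a 240-line
acquisition would give; the package's claims are the relative orderings.

## Numerical choices and degenerate inputs

Unitary FFTs everywhere; the centered-DFT checkerboard modulation is folded
into precomputed sensitivity products inside performance-critical operators.
Rank-deficient separation pixels (determinant below $10^{-10}$ of its scale)
return zero with a warning. Field candidates at the grid edge trigger a
warning when they exceed 1% of signal pixels. `psnr` caps at 200 dB for
identical images; leakage functions reject empty or overlapping ROIs. The
k-space container is an R-native serialized list (truth, field, coils,
k-space by polarity, pattern, metadata) with NIfTI export at 1 mm isotropic
spacing for images.
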