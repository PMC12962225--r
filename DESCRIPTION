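Package: wfsrecon
Title: Water-Fat-Silicone MRI Simulation and Joint Compressed-Sensing Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical-shift-encoded water-fat-silicone (WFS) imaging toolbox for
    bipolar multi-echo fast spin echo acquisitions. Provides a digital phantom and
    k-space simulator, incoherent ky-TE undersampling design with point-spread-function
    analysis, polarity-stacked ESPIRiT calibration and Nyquist ghost-corrected SENSE
    combination, discrete VARPRO-style field and R2-prime mapping, two-stage and joint
    species-domain compressed-sensing reconstructions with chemical-shift displacement
    operators, and image-quality and species-leakage metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
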