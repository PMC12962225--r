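# Nine-peak fat spectral model, chemical shifts relative to the water peak.
# SUBSTITUTABLE CONSTANTS: this is a representative literature-style nine-peak
# triglyceride calibration (dominant methylene peak at -3.40 ppm, methyl at
# -3.80 ppm, olefinic protons just above water). Relative amplitudes are
# renormalized to sum to exactly 1 on load, so any published nine-peak table
# can be dropped in without further changes.
version: 1
peaks_ppm: [0.59, 0.49, -0.50, -1.95, -2.46, -2.68, -3.10, -3.40, -3.80]
relative_amplitudes: [0.048, 0.039, 0.004, 0.012, 0.066, 0.010, 0.059, 0.642, 0.120]
silicone_ppm: -4.9
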