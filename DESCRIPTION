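Package: icr2d
Title: Narrowband Two-Dimensional FT-ICR Mass Spectrometry Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for narrowband two-dimensional Fourier-transform ion
    cyclotron resonance mass spectrometry (2D FT-ICR MS) of modified
    peptides. Provides peptide and electron-capture-dissociation (ECD)
    fragment chemistry with isotopologue fine structure, cyclotron
    frequency calibration and undersampling (foldover) arithmetic, a
    physics-based synthetic 2D transient generator with known ground
    truth, a processing chain (sine-bell apodization, zero-filling, 2D
    Fourier transform, phase correction, randomized low-rank denoising,
    baseline correction), 1D scan peak metrology (parabolic centroiding,
    Lorentzian fitting, FWHM, resolving power, signal-to-noise), and the
    analysis layer for precursor-fragment correlation statistics and
    label-free quantification of near-isobaric proteoforms such as
    acetylated versus trimethylated histone peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
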