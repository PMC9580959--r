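Package: spectralSMLM
Title: Spectrally Displaced Single-Molecule Localization, Multi-Emitter
    Fitting and Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolbox for multidimensional (x, y, z, t, lambda)
    single-molecule localization microscopy acquired on a dual-camera
    spectral setup. A low-dispersion prism in the second detection path
    shifts each emitter's image in proportion to its mean emission
    wavelength; pairing the localizations of the two synchronized channels
    therefore yields a wavelength for every molecule at no photon cost.
    The package provides wavelet-based spot detection and elliptical
    Gaussian fitting with astigmatism-based axial assignment, third-order
    polynomial channel registration and fiducial drift correction,
    dispersion calibration and wavelength assignment, spectrally-informed
    single/double-emitter fitting for overlapping molecules, trajectory
    linking with MSD-based diffusion analysis, and a dual-camera
    acquisition simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
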