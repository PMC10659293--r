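Package: sfsc
Title: Self Fourier Shell Correlation for Single-Measurement Resolution
    Estimation and Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Fourier shell correlation (FSC) and spectral
    signal-to-noise ratio (SSNR) of a 1-D signal, 2-D image or 3-D volume
    from a single noisy measurement.  The self FSC (SFSC) is computed from
    per-axis even/odd decimated copies of the measurement with a half-voxel
    phase-shift alignment, a variance rescaling that maps its expectation
    onto the standard FSC, noise whitening from signal-free regions, and a
    Fourier zero-padding upsampling step with noise subtraction for signals
    with slowly decaying spectra.  Downstream tools include resolution
    determination at a correlation threshold, data-driven Wiener filtering
    of tomograms and maps, a Gaussian random-field generator with B-factor
    spectral decay for validation, and MRC/CCP4 volume input/output with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
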