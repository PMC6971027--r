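Package: clamsim
Title: Simulation and Reconstruction for Coded Light-Sheet Array Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulator-plus-reconstruction toolkit for coded light-sheet
    array microscopy (CLAM), a parallelized volumetric fluorescence imaging
    scheme. Models the angle-misaligned mirror pair ("infinity mirror") that
    splits an input light cone into an array of delayed virtual sources and
    light sheets; plans orthogonal frequency-division multiplexed (OFDM)
    intensity codes subject to camera Nyquist and harmonic design rules;
    synthesizes multiplexed camera frame sequences from synthetic fluorophore
    phantoms with depth-dependent detection blur, scattering attenuation,
    speckle, photon shot noise and read noise; and reconstructs 3D volumes by
    per-pixel short-time Fourier demodulation, frequency-to-depth calibration,
    axial boxcar smoothing and Richardson-Lucy deconvolution. Includes bead
    and scattering phantom generators, a Mie solver for reduced scattering
    coefficients, and point-spread-function, depth-of-field, signal-to-noise
    and photobleaching metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
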