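Package: rgcspeed
Title: Speed Tuning and Motion Decoding in Retinal Ganglion Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for speed selectivity of retinal ganglion
    cells under stimuli of graded spatial-frequency bandwidth. Generates
    drifting gratings, band-limited random-phase motion textures (Motion
    Clouds) and white-noise checkerboards with physical calibration;
    simulates linear-nonlinear Poisson ganglion-cell populations as ground
    truth; estimates receptive fields by spike-triggered averaging with
    elliptical spatial fits and difference-of-cascades temporal fits;
    quantifies speed tuning with skewed log-Gaussian fits, a standardized
    F1 modulation screen and population sparseness; and decodes stimulus
    speed from linearly reconstructed space-time images through a
    quadrature motion-energy filter bank with opponent subtraction and
    winner-takes-all readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
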