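Package: fouriertomo
Title: Fourier-Grid Iterative Tomographic Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tomographic reconstruction of a 3D volume from a tilt series of 2D
    projections at arbitrary Euler orientations. Projections are gridded onto an
    oversampled 3D Fourier grid by exact discrete Fourier summation (or a faster
    FFT scatter mode) with inverse-distance weighting, and the volume is recovered
    by alternating projections between real space (support and positivity) and
    reciprocal space (measured-data constraint), with R-factor and free R-factor
    convergence monitoring, an optional resolution extension/suppression schedule,
    and projection-matching refinement of the tilt angles. Includes a Fourier-slice
    forward projector, synthetic phantoms and noise models, Fourier shell
    correlation, tilt-series preprocessing, and MRC2014 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    fftwtools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
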