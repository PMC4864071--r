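Package: dtwspectrum
Title: Dynamic-Time-Warping Spectra and Trial-Wise Measures of Neural Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Template-based spectral estimation for EEG by sweeping sinusoidal
    templates across a frequency band with banded dynamic time warping (the
    DTW-spectrum), together with companion trial-wise measures of neural
    dynamics: a matched direct-DFT spectrum, one-step MLP prediction error,
    EEG microstate length and mean global field power, and neuronal
    avalanche/cascade length. A GLM and permutation statistical layer
    cross-predicts the measures across subjects in task versus rest blocks,
    and a seeded synthetic-data generator emulates the block-design
    multichannel EEG the measures are defined on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), mclust, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'avalanches.R'
    'dtw.R'
    'dtwspectrum-package.R'
    'glm_stats.R'
    'io.R'
    'microstates.R'
    'pipeline.R'
    'predictor.R'
    'spectra.R'
    'synthetic.R'
    'utils.R'
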