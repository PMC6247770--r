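Package: mpcasl
Title: Multiphase Pseudocontinuous Arterial Spin Labelling for the Mouse Brain
Version: 0.1.0
Authors@R: person("MPCASL", "Developers", role = c("aut", "cre"),
    email = "mpcasl@example.org")
Description: Tools for quantitative cerebral blood flow (CBF) measurement in
    the mouse brain with multiphase pseudocontinuous arterial spin labelling
    (MP pCASL). Provides a Bloch-equation simulator of pCASL labelling
    efficiency for spins flowing through the labelling plane, the Buxton
    general kinetic model (forward and inverse) with M0 calibration and
    multi-delay bolus-arrival-time fitting, the multiphase analysis chain
    (modified-Fermi phase fitting, angle-aware smoothing, SLIC-style
    supervoxel clustering, high-SNR phase re-estimation and perfusion-weighted
    amplitude mapping), a digital mouse-brain/tumour phantom generator with
    ground truth for end-to-end validation, and quantitative autoradiography
    and immunohistochemistry densitometry utilities (film calibration,
    Kety-model CBF, projective alignment, positive-pixel area fraction and
    ROI statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
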