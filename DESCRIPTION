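Package: epidscatter
Title: Tri-Hybrid Estimation of Patient-Generated Scatter Fluence at an EPID
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the patient-generated scattered photon energy fluence
    entering an electronic portal imaging device (EPID) with a tri-hybrid
    method: an analytical Klein-Nishina/Compton-kinematics integration for
    singly scattered photons, a hybrid Monte Carlo/next-event-estimation
    method for multiply scattered photons, and a pencil-beam scatter-kernel
    convolution/superposition for electron-interaction-generated
    (bremsstrahlung and positron-annihilation) photons.  Ships a
    scatter-order-tagging voxel photon Monte Carlo that serves as the
    gold-standard oracle, procedural water/pelvis/thorax voxel phantoms,
    parametric 6 and 18 MV beam spectra, exact Siddon ray tracing, and a
    validation harness (percent-difference images, relative RMSE,
    computational efficiency, error budgets, sampling sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
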