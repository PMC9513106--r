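Package: turbmri
Title: Synthesis and Reconstruction of Multipoint 4D Flow MRI of Turbulent Flow
Version: 0.1.0
Authors@R:
    person("turbmri", "maintainers", email = "maintainers@turbmri.dev",
           role = c("aut", "cre"))
Description: Forward simulation and reconstruction of multipoint (multi-VENC)
    phase-contrast 4D flow MRI of turbulent flow. From gridded ground-truth
    mean-velocity and Reynolds-stress fields -- produced by a built-in analytic
    stenotic-jet phantom or loaded from CFD exports -- the package band-limits
    the fields with a truncated Gaussian modulation transfer function,
    generates complex velocity-encoded MR signals under a scan-time-budget
    noise model, reconstructs velocity, Reynolds stress tensor, turbulent
    kinetic energy and kinetic energy maps, and quantifies resolution, SNR and
    time-averaging errors against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
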