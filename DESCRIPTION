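Package: decbct
Title: Dual-Energy Cone-Beam CT Simulation and Electron-Density Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end simulator and reconstruction toolkit for
    projection-domain dual-energy cone-beam CT electron-density imaging.
    Provides polychromatic forward projection of analytic cylinder phantoms
    at two tube potentials, graphite/aluminium basis-material decomposition
    of the dual-energy log-projections through a look-up table with Newton
    refinement, fan-beam FBP and FDK cone-beam reconstruction of the
    basis-coefficient images, voxel-wise electron-density synthesis, and
    beam-hardening (cupping) evaluation with ROI statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
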