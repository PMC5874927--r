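Package: dtsalign
Title: Digital Tomosynthesis Reconstruction and Registration for Patient Positioning
Version: 0.1.0
Authors@R:
    person("DTS", "Maintainers", email = "maintainers@dtsalign.org", role = c("aut", "cre"))
Description: Tools for image-guided patient positioning with digital
    tomosynthesis (DTS). Forward-projects a planning CT volume into
    digitally reconstructed radiographs (DRRs) under a cone-beam
    on-board-imager geometry, reconstructs coronal and sagittal DTS plane
    stacks from narrow-arc projection sets by FDK-style filtered
    back-projection, and recovers three-dimensional couch shifts by a
    two-session (coronal + sagittal) translational registration of onboard
    versus reference DTS. Includes digital cube and pelvis phantoms with
    known rigid shifts, validation metrics (sub-pixel edge-length
    measurement, correlation and subtraction-image statistics), a
    brute-force per-ray reference engine alongside a fast vectorized
    engine for both projection and reconstruction, raw+JSON volume and
    projection I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
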