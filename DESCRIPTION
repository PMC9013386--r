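Package: magcircuit
Title: Magnetophoretic Circuit Design, Bead Transport Simulation and
    Bead-Pair Assay Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models patterned micromagnet "drop-shape" tracks and bend
    designs for single-bead magnetophoretic transport chips driven by a
    rotating conical magnetic field.  Computes the magnetostatic stray
    field of soft thin-film magnets with an analytic surface-charge model,
    builds dipolar potential-energy landscapes and path profiles, and
    integrates overdamped bead dynamics with pairwise dipole interactions
    to extract transport speeds, critical frequencies and geometric design
    rules.  Also implements the single-pair bead-counting assay readout:
    synthetic chamber micrographs with ground truth, Laplacian-of-Gaussian
    bead detection, pair classification, dose-response summaries and the
    in-plane versus conical field background-pair comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    mgcv,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
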