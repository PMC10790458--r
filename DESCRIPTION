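Package: passs
Title: Patient-Specific Signaling Signatures from Phosphoproteomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Surprisal analysis of phosphotyrosine quantification matrices:
    decomposes natural-log intensities into a steady-state term plus ordered
    unbalanced processes (site weights times sample amplitudes), gates process
    amplitudes against a simulated measurement-noise null to form per-sample
    signaling signatures and sign barcodes, extracts signed weight tails with
    their protein-interaction subnetworks, and translates each sample's active
    processes into ranked druggable targets for mono- or combination therapy.
    Includes a synthetic-cohort generator with planted orthogonal processes
    for ground-truth validation, and an end-to-end pipeline with stable
    on-disk outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
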