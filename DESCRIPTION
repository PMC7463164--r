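Package: optodereg
Title: Photogrammetry-Based fNIRS Optode Registration and Validation Metrics
Version: 0.1.0
Authors@R:
    person("Optodereg", "Developers", email = "optodereg@example.org",
           role = c("aut", "cre"))
Description: Registers functional near-infrared spectroscopy (fNIRS) optode
    positions digitized on a photogrammetric head-surface reconstruction into
    MNI space via a landmark-based affine transform (nasion, inion, Cz and the
    two preauricular points), projects scalp positions onto a cortical surface,
    and builds source-detector channel tables.  Ships the validation metric
    suite used to compare registration methods: per-optode composite standard
    deviation, between-method displacement, 20-mm sphere channel overlap, and
    Monte-Carlo spherical sampling against a parcellation atlas for anatomical
    region estimation.  Includes a synthetic head/cap/atlas generator with
    known ground truth so the whole pipeline is testable without downloads,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
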