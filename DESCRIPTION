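Package: chromaleon
Title: Chromatographic Chameleonicity, Conformer Property Space and Oral
    Bioavailability Descriptors for Beyond-Rule-of-5 Degraders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the chromatographic physicochemical descriptor suite
    used to profile molecular chameleons such as PROTACs (capacity factors,
    BRlogD, log kw IAM, delta log kw IAM, Chamelogk, EPSA-to-TPSA ratio,
    pH-retention ionization classing), noncompartmental oral bioavailability
    (dose-normalized AUC and F%), per-conformer 3D descriptors (radius of
    gyration, Shrake-Rupley solvent-accessible surface area, 3D polar
    surface area at probe radii 0 and 1.4 Angstrom, intramolecular hydrogen
    bonds) and ensemble property-space summaries (medians, 2D density maps,
    density-maximum conformers, polar/nonpolar solvent contrasts), together
    with the descriptor-efflux-bioavailability relationship layer and seeded
    synthetic-data generators so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
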