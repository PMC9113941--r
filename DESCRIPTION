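Package: nucgeom
Title: Geometry of Nucleosome Arrays, Linker DNA Trajectories and H1
    Binding Compatibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative geometry of nucleosome arrays from atomic or
    coarse-grained models. Builds per-nucleosome reference frames from DNA
    base-pair centroids, measures the linker DNA trajectory angles alpha and
    beta by plane projection, computes their deviations (delta-alpha,
    delta-beta) from a rigid-body superposed reference mononucleosome,
    quantifies nucleosome-nucleosome stacking (center distance, disc-normal
    angle, dyad tilt, lateral offset), classifies nucleosomes as compatible or
    incompatible with on-dyad linker histone H1 binding from delta-beta, and
    screens coarse steric clashes against an H1 footprint. Includes a
    synthetic coarse-grained array generator with analytically known ground
    truth covering nucleosome repeat lengths 177-207 bp.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
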