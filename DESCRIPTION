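Package: craniosh
Title: Cranial Asymmetry Quantification from 3D Head Models via Spherical Harmonics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies deformational plagiocephaly (DP) from infant head 3D
    point clouds. Registers a sparse (~530 point) cranial surface scan into an
    anatomical frame defined by three landmarks, fits the ideal axis-aligned
    triaxial ellipsoid by linear least squares, computes signed orthogonal
    point-to-ellipsoid distances via foot-point iteration, and expands the
    distance field in 4-pi-normalized real spherical harmonics. The degree-2,
    order -2 coefficient at maximum degree 4 serves as an asymmetry index and
    screening statistic, alongside classical anthropometric indexes (cephalic
    index, cranial vault asymmetry index, oblique cranial length ratio) and
    their anterior/posterior decompositions. Includes threshold-based
    screening, cohort-level group statistics, a synthetic-head generator with
    known planted deformations, and point-cloud/landmark/report I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    car,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
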