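Package: histoslice
Title: Landmark Registration of Brain-Slice Histology to Mouse Atlases and
    Cell Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless pipeline for registering 2D brain-slice histology
    images to a 3D mouse brain reference atlas from user-supplied landmark
    pairs, applying the identical geometric warp to pre-counted cell
    coordinates, assigning each cell to a named brain structure under either
    the Allen Common Coordinate Framework ontology or the modified
    Franklin-Paxinos (Chon) labels, and producing per-slice and per-brain
    region tallies plus a 3D point cloud in atlas space. Includes oblique
    virtual sectioning of annotation volumes with dorsoventral and
    mediolateral tilt, affine, projective and thin-plate-spline landmark
    transforms, synthetic fixture generation for download-free testing, and
    a batch command-line interface over a project directory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
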