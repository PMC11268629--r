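Package: cryopick
Title: Geometry-Based Particle Picking and Annotation Tools for Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns sparse manual annotations of cryo-electron tomograms
    (clicked points, per-slice point strips, sparsely painted label slices)
    into dense, regularly spaced data: arc-length parametrised 3D splines
    with twist-free moving frames, helical lattices of oriented particle
    poses along filaments, spline-grid surface models with per-node normals,
    surface-guided volume resampling ("straightening"), and signed-distance
    -field label interpolation. Reads and writes the standard
    subtomogram-averaging particle formats (Relion STAR, Dynamo TBL,
    EMAN/CrYOLO BOX and CBOX) and image formats (MRC2014, TIFF, EM), with
    Euler-angle convention conversion and format guessing. Includes
    deterministic synthetic fixture generators for testing and tutorials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    tools,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
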