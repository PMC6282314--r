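Package: alphacomplexity
Title: Shape Complexity of 3D Structures via Alpha-Shape Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits families of three-dimensional alpha-shapes to point clouds
    derived from segmented micro-CT volumes and locates the 'optimal'
    refinement coefficient at which alpha-shape volume equals the raw voxel
    volume of the specimen, a landmark-free measure of topographic shape
    complexity. The alpha radius is scaled by a per-specimen reference length
    (preferably the mean distance of each point to its 100 nearest
    neighbours) so that refinement coefficients are comparable across
    specimens of different absolute size. Includes micro-CT stack
    preprocessing (automated thresholding, slice-wise morphological closing
    and hole filling, voxel-to-point-cloud conversion, seeded downsampling),
    breakdown diagnostics and coarsest-contribution labelling, comparator
    metrics (three-dimensional dissection index from decimated isosurface
    meshes and box-counting fractal dimension with local-slope plateau
    diagnostics), voxelised geometric phantoms with analytic volumes for
    validation, and batch processing with point-cloud-density sensitivity
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    EBImage,
    tiff,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
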