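# alphacomplexity

Landmark-free measurement of 3D shape complexity from segmented micro-CT
volumes, built around alpha-shape refinement.

Irregular biological structures — penis bones (bacula), corals, tooth
crowns, root systems — often lack the homologous landmarks that geometric
morphometrics needs. This package quantifies how *topographically complex*
such a structure is, directly from its binarised CT stack, by fitting the
whole family of alpha-shapes to the voxel point cloud and asking how much
refinement the fit needs before its volume matches the specimen's true
voxel volume. It is written for morphologists, evolutionary biologists and
anyone comparing complex 3D forms across specimens of very different size
and shape.

## The metric

An alpha-complex is the subcomplex of the Delaunay tetrahedralization whose
tetrahedra fit inside a probe sphere of radius α; its boundary is the
alpha-shape, ranging from the convex hull (α = ∞) down to fragmented fine
fits. The probe radius is scaled per specimen,

    α = k · l_ref

with `k` a dimensionless refinement coefficient and `l_ref` the cloud's
reference length (by default the mean distance of each point to its 100
nearest neighbours). Coarse fits overestimate the volume of a concave
object; over-refined fits underestimate it. The **optimal refinement
coefficient k\*** is the `k` at which alpha-shape volume crosses 100% of
the raw voxel volume (foreground count × voxel size³). Smaller k\* = more
complex shape, independent of absolute size. Comparator metrics are
included: the 3D dissection index √SA / ∛V from a decimated 10,000-face
isosurface mesh, and the box-counting fractal dimension, slope of log N(s)
vs log(1/s), with local-slope plateau diagnostics.

The Delaunay/alpha-complex engine, quickhull, marching-tetrahedra
isosurfacing and quadric decimation are implemented in C++ (Rcpp) inside
the package.

## Worked example

Every stage is testable without scan data through voxelised phantoms with
closed-form volumes. A capsule with a broad longitudinal groove (analytic
volume 147.54 mm³), voxelised at 0.1 mm and pushed through the default
pipeline:

```r
library(alphacomplexity)

spec <- shape_spec("grooved_capsule", radius = 2, length = 10,
                   groove_width = 1.2, groove_depth = 1, voxel_size_mm = 0.1)
vol  <- make_shape(spec)
vol
#> <binary_volume> 44x144x44 voxels @ 0.1 mm, 148352 foreground (148.4 mm^3)

rep <- process_specimen(vol, run_config(seed = 11, downsample_n = 1e4),
                        id = "grooved_capsule")
rep
#> <complexity_report> grooved_capsule
#>   raw volume   148.544 mm^3 (10000 points, seed 11)
#>   l_ref        0.570472 mm (knn_mean)
#>   optimal k*   2.19321 (converged)
#>   breakdown k  0.5672
#>   DI           2.7205
#>   FD           2.3918 (plateau absent)
```

Reading the report: the voxel volume recovered the analytic volume to
within 0.7%; the alpha fit needed refinement k\* ≈ 2.2 — at that
refinement, alpha volume equals raw volume to the 1e-4 stopping tolerance —
and the fit fragments below k ≈ 0.57. A smooth curved rod of the same
material processes to k\* ≈ 8 (simpler: a coarser fit already recovers its
volume), while adding a groove *and* curvature drops k\* to ≈ 1.4; the
dissection index exceeds the spherical minimum 2.199, and the absence of a
local-slope plateau says this object should not be called fractal.
`plot(rep$curve)` draws the alpha curve with its 100% crossing and
breakdown point.

Note one geometric property: for a *convex* voxelised solid (perfect
sphere, straight capsule) the hull of the voxel-centre cloud is strictly
smaller than the voxel volume, so the 100% crossing cannot exist and
`optimal_k()` signals a classed `no_crossing` error. The metric presumes
concavity — which every real specimen of interest has.

A command-line driver with `run`, `preprocess`, `curve`, `optimal`,
`metrics`, `sweep` and `fixtures` subcommands is installed at
`inst/cli/alphacomplexity.R`:

```sh
Rscript inst/cli/alphacomplexity.R run --seed 1 --voxel-size 0.1 stack.tif
```

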