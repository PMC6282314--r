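---
title: "Measuring 3D shape complexity with alpha-shape refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D shape complexity with alpha-shape refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Many biological structures — carnivoran bacula are the motivating example —
are too irregular for landmark-based morphometrics: there are no homologous
points to digitise. This package measures their *topographic complexity*
instead, using the family of alpha-shapes fitted to a point cloud sampled
from the solid.

An alpha-complex is the subcomplex of the Delaunay tetrahedralization whose
simplices fit inside a probe sphere of radius $\alpha$; its boundary is the
alpha-shape. As $\alpha \to \infty$ the alpha-shape is the convex hull; as
$\alpha$ shrinks the fit tightens, resolves concave features (curvature,
grooves, pits) in order of their size, and finally fragments ("breaks
down") once $\alpha$ slips below the inter-point spacing. Because coarse
fits overestimate the volume of a concave object and over-refined fits
underestimate it, there is a refinement at which alpha-shape volume equals
the true (voxel) volume of the specimen. That refinement is the complexity
metric: complex shapes need a fine fit to recover their volume, simple
shapes a coarse one.

Absolute $\alpha$ values are not comparable across specimens of different
size, so the probe radius is scaled per specimen:

$$\alpha = k \, l_{\mathrm{ref}}$$

where $k$ is the dimensionless *refinement coefficient* and
$l_{\mathrm{ref}}$ a reference length summarising the cloud's scale. The
*optimal refinement coefficient* $k^\*$ — where alpha volume crosses 100% of
raw voxel volume — is then size-free: two identical shapes at different
absolute sizes give the same $k^\*$ (a property the test suite asserts to
1%). Smaller $k^\*$ means a more complex shape.

## The pipeline

1. **Binarise** the grayscale stack by Otsu's threshold on the pooled
   histogram (already-binary stacks pass through).
2. **Close** each 2D slice with a disc of radius 6 px (default), bridging
   small segmentation gaps in the outer contour so internal cavities become
   well-defined holes. Closing is computed with a background margin at
   least as wide as the brush, because digital erosion treats out-of-image
   pixels as foreground.
3. **Fill** internal cavities: background pixels unreachable from the slice
   edge are flood-filled, slice by slice (default). A 3D fill
   (6-connected) is available for canals that are not 2D holes in any
   single slice. The analysis targets external form, so void spaces are
   treated as solid.
4. **Raw volume** = foreground voxel count × voxel size³, recorded *before*
   downsampling.
5. **Point cloud**: one point per foreground voxel centre, interior points
   included — the cloud represents the solid, not a surface scan.
6. **Downsample** to 100,000 points (default) with an explicit seed, so all
   specimens in a comparison carry equal detail.
7. **Reference length**: mean distance of each point to its 100 nearest
   neighbours (default; kd-tree via RANN). Bounding-box-diagonal and
   mean-distance-to-centroid estimators are provided for comparison, but
   the knn estimator tracks the inter-point spacing of the downsampled
   cloud, which makes breakdown happen at a consistent $k$ across
   specimens.
8. **Alpha curve**: the Delaunay tetrahedralization is computed once; each
   of 200 log-uniform refinement coefficients in $[0.1, 10^4]$ is then a
   pure filter on precomputed circumradii. Volume, % of raw volume and
   component count are recorded per $k$.
9. **Optimal search**: a pre-sweep brackets the (unique, by monotonicity)
   100% crossing; Nelder–Mead over $\log_{10} k$, seeded from the coarse
   side, minimises the volume mismatch until both stopping conditions hold
   (volume and $k$ conditions, below).
10. **Comparators**: 3D dissection index
    $\sqrt{SA}/\sqrt[3]{V}$ from a 10,000-face isosurface mesh, and
    box-counting fractal dimension with local-slope diagnostics.

```{r example}
library(alphacomplexity)

spec <- shape_spec("grooved_capsule", radius = 2, length = 10,
                   groove_width = 1.2, groove_depth = 1, voxel_size_mm = 0.1)
vol  <- make_shape(spec)
rep  <- process_specimen(vol, run_config(seed = 11, downsample_n = 1e4),
                         id = "grooved")
rep
plot(rep$curve)
```

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| closing radius | 6 | px | smallest disc that reliably closes the outer (periosteal) contour in the micro-CT material this pipeline targets; phantoms need no closing (`0`) |
| downsample size | 100,000 | points | equalises detail across specimens; $k^\*$ *depends on this choice* (see sensitivity) |
| reference length | knn mean, 100 neighbours | mm | scales with inter-point spacing; makes breakdown $k$ specimen-invariant |
| refinement grid | 200 points, $[0.1, 10^4]$, log-uniform | — | spans convex-hull fits to past-breakdown fits |
| stopping tolerance | $10^{-4}$ | relative / $k$ units | see "numerical choices" |
| mesh budget | 10,000 faces | — | conventional budget for mesh-based complexity metrics |

## Numerical choices

* **Alpha criterion.** A tetrahedron is kept when its circumradius is at
  most $\alpha$; volume is the sum over kept tetrahedra and the boundary is
  the set of faces with exactly one kept tetrahedron. This is the
  convention of the classic alpha-volume implementations. The singular
  edges/faces of the full alpha-complex theory carry no volume and are not
  represented. Ties (`circumradius == alpha`) are kept, which makes the
  nesting invariant — kept sets only grow with $\alpha$ — exact, and the
  volume curve exactly monotone.
* **Stopping conditions.** The classic dual rule is applied: stop when the
  volume mismatch is below $10^{-4}$ *and* the optimiser's step in $k$ is
  below $10^{-4}$. The volume condition is read as *relative*
  ($|V_\alpha - V_{\mathrm{raw}}|/V_{\mathrm{raw}}$): an absolute reading in
  mm³ would be unattainable for small specimens and vacuous for large ones.
  Because $V(k)$ is a step function (tetrahedra enter at discrete radii),
  the volume condition is met only where steps near the crossing are finer
  than $10^{-4}$ relative; otherwise the search returns its best point
  flagged `converged = FALSE`.
* **Search variable.** $\log_{10} k$, matching the logarithmic structure of
  the curve; the simplex starts at the grid point bracketing the crossing,
  one grid step wide, and is clamped to the grid bounds.
* **Delaunay engine.** Incremental Bowyer–Watson with a single symbolic
  vertex at infinity (no finite super-tetrahedron, hence no far-coordinate
  precision loss). Predicates are double-precision determinants with
  per-call magnitude estimates; decisions within `1e-12` of the magnitude
  are treated as "outside" (ties-out), and a cavity star-shape repair step
  guarantees a valid triangulation on the exactly-cospherical and coplanar
  point groups that voxel grids produce. The insertion order is a fixed
  pseudo-random permutation, so the triangulation is deterministic. On
  random clouds the engine reproduces the brute-force empty-circumsphere
  definition exactly (tested), and its total volume matches an independent
  quickhull to $10^{-9}$ relative.
* **Degenerate tetrahedra.** Tetrahedra flatter than $10^{-12}$ × (bounding
  box diagonal)³ have numerically meaningless circumradii and nil volume;
  they are excluded at finite $\alpha$ (circumradius set to $\infty$) and
  participate only in the convex-hull limit.
* **Circumradii** are computed by solving the circumcentre linear system in
  coordinates translated to the first vertex — numerically stabler than
  edge-length product formulas.
* **No jittering.** Grid-degenerate inputs are handled by the tolerance and
  repair machinery, never by perturbing coordinates; downsampling already
  breaks most grid regularity.
* **Box counting** anchors the grid at the array origin and pads to the
  next power of two; grid placement is a known arbitrary choice of the
  method, so it is fixed and documented rather than optimised. The fit
  range defaults to box sizes from 1 voxel to half the padded extent, and
  the local slopes between successive sizes are always reported: without a
  plateau (≥ 3 consecutive local slopes within 0.05) the global slope
  should not be read as evidence of fractality.
* **Meshing.** Isosurfaces are extracted by marching tetrahedra over the
  Kuhn 6-tetrahedron cube decomposition (watertight by construction),
  lightly smoothed with Taubin's volume-preserving filter, and decimated by
  quadric-error edge collapse with link-condition and normal-flip guards.

## The phantom suite, and what it can and cannot show

Comparative micro-CT material is rarely redistributable, so validation runs
entirely on voxelised geometric phantoms with closed-form volumes: sphere,
capsule, grooved capsule (rectangular channel along the cylindrical part,
imitating a broad urethral groove), curved rod (capsule swept along a
circular arc; volume by Pappus' theorem), optionally grooved, and a hollow
sphere. Voxel membership is by centre-inclusion, the same semantics as a
binarised CT scan; voxel volume converges to the analytic volume as
resolution grows (within 2% at 10 voxels per radius, tested).

The phantoms exercise the method's core claims: the complexity ordering
(curved + grooved < grooved < curved-only $k^\*$, mirroring the
most-complex → least-complex ranking of real material), scale invariance of
$k^\*$, breakdown consistency, and the density sensitivity (coarser clouds
give coarser $k^\*$ — the coastline paradox). They do *not* imitate real
surface texture, scanning noise, or segmentation artefacts; passing tests
demonstrate correctness of the machinery and the stated invariances, not
field performance on any particular tissue class.

### A geometric limit: convex specimens

For a *convex* voxelised solid the convex hull of the voxel-centre cloud
lies strictly inside the voxel solid, so hull volume < raw volume by
roughly half a voxel's worth of surface shell (several percent at phantom
resolutions). Alpha-shape volume never exceeds hull volume, so the 100%
crossing **cannot exist** for a perfect sphere or straight capsule:
`optimal_k()` raises a classed `no_crossing` error, and
`process_specimen()` records the reason and carries on. This is a real
property of the estimator, not an implementation artefact — the metric
presupposes that coarse fits *over*-estimate volume, which is true exactly
when concavity outweighs the voxel-surface bias. Real skeletal material is
always curved, grooved or rugose enough; among phantoms, the k\*-bearing
test fixtures are therefore the curved and grooved ones, with the plain
capsule's role taken by a gently curved rod.

### Problem sizes

Tests and the acceptance script run phantoms at 0.05–0.1 mm voxels
(≈ 3×10⁴–10⁶ foreground voxels), clouds of 10⁴ points for optimal-k work
(10⁵ for the density sweep), brute-force oracles at ≤ 50 points, and
20 random 500-point clouds for the hull limit. These sizes were chosen so
that every asserted property is in its asymptotic regime while the whole
suite stays fast; the pipeline itself is routinely used at the 10⁵-point
default.

## Known limitations

* $k^\*$ is a function of point-cloud density; only values computed at the
  same downsampling size are comparable (the sensitivity sweep quantifies
  this per specimen).
* Convex or near-convex specimens have no crossing (see above); the method
  is a concavity meter, weighted towards gross concave features rather than
  corrugation-like rugosity.
* Anisotropic voxels are rejected, not resampled.
* Weighted alpha shapes, 2D alpha shapes, and automatic attribution of
  curve steps to named anatomical features are out of scope.
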