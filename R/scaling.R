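# Reference-length scaling and the optimal-refinement search.
#
# Alpha radii are in mm, so a fixed alpha refines a small specimen and
# barely touches a large one.  Scaling alpha by a per-specimen reference
# length, alpha = k * l_ref, makes the dimensionless refinement coefficient
# k comparable across specimens: two identical shapes at different absolute
# sizes reach the same refinement at the same k.

#' Reference length of a point cloud
#'
#' Three estimators of the scalar 'size' of a point cloud used to scale the
#' alpha radius:
#' * `ref_length_bbox()`: diagonal of the axis-aligned bounding box;
#' * `ref_length_centroid()`: mean distance of all points to the centroid;
#' * `ref_length_knn()`: mean over points of the mean distance to each
#'   point's `k_neighbors` nearest neighbours (self excluded) -- the package
#'   default, because it tracks the inter-point spacing of the downsampled
#'   cloud and therefore makes alpha-shape breakdown occur at a consistent
#'   refinement coefficient across specimens.
#'
#' @param pc a [point_cloud()] or n x 3 matrix (n >= 2).
#' @param k_neighbors number of nearest neighbours for `ref_length_knn()`
#'   (default 100; must be smaller than the number of points).
#' @return A `reference_length`: list with `value_mm`, `method`,
#'   `k_neighbors` (knn only) and `n_points`.
#' @name reference_length
NULL

ref_coords <- function(pc, min_pts = 2) {
  coords <- if (inherits(pc, "point_cloud")) pc$coords else as.matrix(pc)
  if (nrow(coords) < min_pts)
    acx_stop("invalid_parameter",
             sprintf("at least %d points are required", min_pts))
  coords
}

new_ref_length <- function(value, method, n, k_neighbors = NULL) {
  if (!is.finite(value) || value <= 0)
    acx_stop("invalid_parameter",
             "reference length is not positive (degenerate cloud?)")
  structure(list(value_mm = value, method = method, k_neighbors = k_neighbors,
                 n_points = n), class = "reference_length")
}

#' @rdname reference_length
#' @export
ref_length_bbox <- function(pc) {
  coords <- ref_coords(pc)
  ext <- apply(coords, 2, range)
  new_ref_length(sqrt(sum((ext[2, ] - ext[1, ])^2)), "bbox_diagonal",
                 nrow(coords))
}

#' @rdname reference_length
#' @export
ref_length_centroid <- function(pc) {
  coords <- ref_coords(pc)
  ctr <- colMeans(coords)
  new_ref_length(mean(sqrt(rowSums(sweep(coords, 2, ctr)^2))), "centroid_mean",
                 nrow(coords))
}

#' @rdname reference_length
#' @export
ref_length_knn <- function(pc, k_neighbors = 100L) {
  coords <- ref_coords(pc)
  k <- as.integer(k_neighbors)
  if (is.na(k) || k < 1 || k >= nrow(coords))
    acx_stop("invalid_parameter",
             "k_neighbors must satisfy 1 <= k_neighbors < n_points")
  nn <- RANN::nn2(coords, coords, k = k + 1L)     # kd-tree; first hit is self
  new_ref_length(mean(rowMeans(nn$nn.dists[, -1, drop = FALSE])), "knn_mean",
                 nrow(coords), k_neighbors = k)
}

#' @export
print.reference_length <- function(x, ...) {
  cat(sprintf("<reference_length> %.6g mm (%s%s, n = %d)\n", x$value_mm,
              x$method,
              if (!is.null(x$k_neighbors)) sprintf(", k = %d", x$k_neighbors)
              else "", x$n_points))
  invisible(x)
}

#' Alpha radius from a refinement coefficient
#'
#' `alpha = k * l_ref`: converts the dimensionless refinement coefficient
#' into an alpha radius in mm.
#'
#' @param k positive refinement coefficient(s).
#' @param l_ref a [reference_length] or a positive number (mm).
#' @return Alpha radius (mm), vectorised over `k`.
#' @export
alpha_from_k <- function(k, l_ref) {
  lv <- if (inherits(l_ref, "reference_length")) l_ref$value_mm else l_ref
  if (!is.numeric(lv) || length(lv) != 1 || lv <= 0)
    acx_stop("invalid_parameter", "l_ref must be a positive length")
  if (!is.numeric(k) || any(is.na(k)) || any(k <= 0))
    acx_stop("invalid_parameter", "k must be strictly positive")
  k * lv
}

#' Refinement-coefficient grid
#'
#' `n` values of the refinement coefficient, evenly spaced on a logarithmic
#' scale between `lo` and `hi` inclusive.  The defaults (200 values from 0.1
#' to 10,000) span coarse fits indistinguishable from the convex hull down
#' to fits beyond breakdown.
#'
#' @param n number of grid values (>= 2).
#' @param lo,hi positive endpoints, `lo < hi`.
#' @return A `refinement_grid`: list with ascending `values`, `n`, `lo`, `hi`.
#' @export
build_grid <- function(n = 200L, lo = 0.1, hi = 10000) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && lo < hi))
    acx_stop("invalid_parameter", "need 0 < lo < hi")
  n <- as.integer(n)
  if (is.na(n) || n < 2) acx_stop("invalid_parameter", "n must be >= 2")
  structure(list(values = exp(seq(log(lo), log(hi), length.out = n)),
                 n = n, lo = lo, hi = hi), class = "refinement_grid")
}

#' Alpha curve: volume and fragmentation across the refinement grid
#'
#' Fits the whole family of alpha-shapes to one cloud (the Delaunay
#' tetrahedralization is computed once and filtered per grid value) and
#' records, for every refinement coefficient, the alpha radius, the
#' alpha-shape volume, that volume as a percentage of the raw voxel volume,
#' and the number of connected components.  The volume column is
#' non-decreasing in `k` by the nesting property of alpha complexes.
#'
#' @param pc a [point_cloud()].
#' @param l_ref a [reference_length] (or positive number, mm).
#' @param raw_volume_mm3 raw voxel volume of the specimen (mm^3).
#' @param grid a [build_grid()] result.
#' @param tri optional precomputed [delaunay_tets()] for `pc`.
#' @param specimen_id identifier stored with the curve.
#' @return An `alpha_curve` data.frame with columns `k`, `alpha_mm`,
#'   `volume_mm3`, `volume_pct_raw`, `n_components`, plus attributes
#'   `l_ref`, `raw_volume_mm3`, `specimen_id`.
#' @export
alpha_curve <- function(pc, l_ref, raw_volume_mm3, grid = build_grid(),
                        tri = NULL, specimen_id = "specimen") {
  stopifnot(inherits(grid, "refinement_grid"))
  if (!is.numeric(raw_volume_mm3) || raw_volume_mm3 <= 0)
    acx_stop("invalid_parameter", "raw_volume_mm3 must be positive")
  if (is.null(tri)) tri <- delaunay_tets(pc)
  alphas <- alpha_from_k(grid$values, l_ref)

  vt <- volume_table(tri)
  vols <- volume_at_alpha(vt, alphas)
  ncomp <- as.integer(cpp_filtration_components(tri$circumradius,
                                                tri$face_tets, alphas))
  out <- data.frame(k = grid$values, alpha_mm = alphas, volume_mm3 = vols,
                    volume_pct_raw = 100 * vols / raw_volume_mm3,
                    n_components = ncomp)
  structure(out, l_ref = l_ref, raw_volume_mm3 = raw_volume_mm3,
            specimen_id = specimen_id, class = c("alpha_curve", "data.frame"))
}

# sorted circumradii with cumulative volumes: V(alpha) by binary search
volume_table <- function(tri) {
  fin <- is.finite(tri$circumradius)
  o <- order(tri$circumradius[fin])
  r <- tri$circumradius[fin][o]
  cv <- cumsum(tri$volume[fin][o])
  list(r = r, cv = cv, total = sum(tri$volume))
}

volume_at_alpha <- function(vt, alphas) {
  out <- numeric(length(alphas))
  inf <- is.infinite(alphas)
  out[inf] <- vt$total
  idx <- findInterval(alphas[!inf], vt$r)
  out[!inf] <- ifelse(idx == 0, 0, vt$cv[pmax(idx, 1L)])
  out
}

#' Optimal refinement coefficient
#'
#' Finds `k*`, the refinement coefficient at which the alpha-shape volume
#' equals the specimen's raw voxel volume -- the package's complexity metric
#' (smaller `k*` = more complex shape).  A coarse pre-sweep over the grid
#' brackets the crossing of 100% raw volume (alpha-shape volume is monotone
#' in `k`, so the crossing is unique); a Nelder-Mead search over
#' `log10(k)`, seeded from the coarse side, then minimises the absolute
#' volume mismatch.  The search stops when both conditions hold: the
#' relative volume mismatch is below `tol` (the `1e-4` volume condition,
#' read as relative so it is meaningful for specimens of any absolute size)
#' and the simplex width in `k` is below `tol`.
#'
#' If the raw volume exceeds the convex-hull volume of the cloud the
#' crossing cannot exist and a `no_crossing` error is raised.  This happens
#' for *convex* voxelised solids: the hull of voxel-centre points lies
#' strictly inside the voxel solid, so coarse alpha-shapes cannot reach the
#' raw volume.  Real specimens with any curvature, grooves or rugosity have
#' hull volumes well above raw volume and are unaffected.
#'
#' @param pc a [point_cloud()].
#' @param l_ref a [reference_length] (or positive number, mm).
#' @param raw_volume_mm3 raw voxel volume (mm^3).
#' @param tol stopping tolerance (both volume, relative, and k).
#' @param grid pre-sweep [build_grid()].
#' @param tri optional precomputed [delaunay_tets()].
#' @param max_iter Nelder-Mead iteration cap.
#' @return An `optimal_result`: list with `k_star`, `alpha_star_mm`,
#'   `volume_at_k_star`, `rel_volume_mismatch`, `iterations`, `converged`,
#'   `tol`.
#' @export
optimal_k <- function(pc, l_ref, raw_volume_mm3, tol = 1e-4,
                      grid = build_grid(), tri = NULL, max_iter = 500L) {
  if (is.null(tri)) tri <- delaunay_tets(pc)
  lv <- if (inherits(l_ref, "reference_length")) l_ref$value_mm else l_ref
  if (!is.numeric(raw_volume_mm3) || raw_volume_mm3 <= 0)
    acx_stop("invalid_parameter", "raw_volume_mm3 must be positive")
  vt <- volume_table(tri)
  hull_vol <- vt$total
  if (raw_volume_mm3 > hull_vol * (1 + 1e-12))
    acx_stop("no_crossing", sprintf(
      "raw volume (%.6g) exceeds the convex-hull volume of the cloud (%.6g): alpha volume can never reach 100%% of raw volume",
      raw_volume_mm3, hull_vol))

  f <- function(x) {            # x = log10(k)
    if (x < log10(grid$lo) || x > log10(grid$hi)) return(Inf)
    abs(volume_at_alpha(vt, 10^x * lv) - raw_volume_mm3) / raw_volume_mm3
  }

  # coarse pre-sweep: bracket the unique crossing from the coarse side
  gv <- grid$values
  vols <- volume_at_alpha(vt, gv * lv)
  above <- vols >= raw_volume_mm3
  i0 <- if (any(above)) min(which(above)) else grid$n
  step <- log10(gv[2] / gv[1])
  x1 <- log10(gv[i0])
  x2 <- x1 + if (i0 < grid$n) step else -step

  f1 <- f(x1); f2 <- f(x2)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (f2 < f1) { tmp <- x1; x1 <- x2; x2 <- tmp; tmp <- f1; f1 <- f2; f2 <- tmp }
    # stopping: both the volume and the k condition
    if (f1 < tol && abs(10^x1 - 10^x2) < tol) { converged <- TRUE; break }
    xr <- x1 + (x1 - x2)            # reflect worst through best
    fr <- f(xr)
    if (fr < f1) {
      xe <- x1 + 2 * (x1 - x2)      # expand
      fe <- f(xe)
      if (fe < fr) { x2 <- xe; f2 <- fe } else { x2 <- xr; f2 <- fr }
    } else {
      xc <- x1 + 0.5 * (x2 - x1)    # contract
      fc <- f(xc)
      if (fc <= f2) { x2 <- xc; f2 <- fc }
      else { x2 <- x1 + 0.5 * (x2 - x1); f2 <- f(x2) }  # shrink
    }
  }
  if (f2 < f1) { x1 <- x2; f1 <- f2 }

  structure(list(k_star = 10^x1, alpha_star_mm = 10^x1 * lv,
                 volume_at_k_star = volume_at_alpha(vt, 10^x1 * lv),
                 rel_volume_mismatch = f1, iterations = iter,
                 converged = converged, tol = tol),
            class = "optimal_result")
}

#' @export
print.optimal_result <- function(x, ...) {
  cat(sprintf(
    "<optimal_result> k* = %.6g (alpha %.6g mm), volume mismatch %.2e, %s after %d iterations\n",
    x$k_star, x$alpha_star_mm, x$rel_volume_mismatch,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Breakdown refinement coefficient
#'
#' The largest grid refinement coefficient at which the alpha shape is not a
#' single connected volume -- the point where the alpha radius slips inside
#' the point cloud and the fit fragments (or, at very fine alpha, vanishes).
#'
#' @param curve an [alpha_curve()] result.
#' @return The breakdown `k`, or `NA` if the shape never fragments on the
#'   grid.
#' @export
breakdown_k <- function(curve) {
  stopifnot(inherits(curve, "alpha_curve"))
  bad <- curve$n_components != 1L
  if (!any(bad)) return(NA_real_)
  max(curve$k[bad])
}

#' Coarsest alpha-shape contribution per point
#'
#' For every point, the largest grid refinement coefficient at which the
#' point is a vertex of at least one boundary triangle of the alpha shape.
#' Points buried so deep they never reach a boundary are labelled interior
#' (`NA`).  Deeply recessed features (groove floors, pits) only join the
#' boundary at fine refinements, so small labels flag locally complex
#' regions.
#'
#' Each Delaunay face is a boundary face exactly when one of its (up to two)
#' incident tets is kept, i.e. for alpha in `[r1, r2)` with `r1 <= r2` the
#' incident circumradii (`r2 = Inf` for hull faces); per-point labels are
#' then interval maxima over incident faces, no per-alpha recomputation
#' needed.
#'
#' @param pc a [point_cloud()] (used only when `tri` is missing).
#' @param l_ref a [reference_length] or positive number (mm).
#' @param grid a [build_grid()] result.
#' @param tri optional precomputed [delaunay_tets()].
#' @return Data frame with `point`, `coarsest_k` (NA = interior).
#' @export
coarsest_contribution <- function(pc, l_ref, grid = build_grid(), tri = NULL) {
  if (is.null(tri)) tri <- delaunay_tets(pc)
  stopifnot(inherits(grid, "refinement_grid"))
  alphas <- alpha_from_k(grid$values, l_ref)
  n <- nrow(tri$points)

  t1 <- tri$face_tets[, 1]
  t2 <- tri$face_tets[, 2]
  r1 <- tri$circumradius[t1]
  r2 <- ifelse(t2 == 0L, Inf, tri$circumradius[pmax(t2, 1L)])
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  ok <- is.finite(lo)                       # faces that ever reach a boundary

  # largest grid alpha strictly below hi and at least lo
  cnt <- findInterval(hi, alphas)           # alphas[cnt] <= hi
  tie <- cnt >= 1 & cnt <= length(alphas) & ok
  tie[tie] <- alphas[cnt[tie]] >= hi[tie]   # exact tie: face already interior
  cnt <- cnt - as.integer(tie)
  good <- ok & cnt >= 1
  good[good] <- alphas[cnt[good]] >= lo[good]

  face_k <- rep(NA_real_, length(lo))
  face_k[good] <- grid$values[cnt[good]]

  ids <- c(tri$faces[, 1], tri$faces[, 2], tri$faces[, 3])
  vals <- rep(face_k, 3)
  keep <- !is.na(vals)
  ids <- ids[keep]; vals <- vals[keep]
  res <- rep(NA_real_, n)
  o <- order(ids, vals)                     # last write per id wins = max
  res[ids[o]] <- vals[o]
  data.frame(point = seq_len(n), coarsest_k = res)
}
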