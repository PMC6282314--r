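# Voxelised geometric phantoms with analytic volumes.  Real comparative
# material (museum micro-CT scans) is rarely redistributable, so every
# downstream stage is validated against these primitives instead: voxel
# membership is decided by centre-inclusion in the analytic solid, matching
# the semantics of a binarised CT scan, and each solid has a closed-form
# volume to test against.

#' Specify a synthetic voxelised shape
#'
#' Describes one of five analytic solids to be voxelised by [make_shape()]:
#' a sphere, a capsule (cylinder with hemispherical caps), a grooved capsule
#' (capsule with a rectangular-section channel cut along the cylindrical part
#' of one side, mimicking a broad urethral groove), a curved rod (capsule
#' swept along a circular arc, optionally grooved along its outer face), and
#' a hollow sphere (spherical shell).
#'
#' All lengths are in mm.  Every feature intended to be resolved must span at
#' least 3 voxels (the usual rule of thumb for feature resolution in voxel
#' data); specifications violating this raise an `invalid_shape_spec` error.
#'
#' @param kind one of `"sphere"`, `"capsule"`, `"grooved_capsule"`,
#'   `"curved_rod"`, `"hollow_sphere"`.
#' @param radius tube/sphere radius (mm); outer radius for `hollow_sphere`.
#' @param length cylindrical length for capsules; arc length of the centre
#'   path for `curved_rod` (mm).
#' @param arc_radius radius of the circular arc swept by a `curved_rod` (mm);
#'   must exceed `radius`.
#' @param groove_width,groove_depth rectangular groove cross-section (mm);
#'   used by `grooved_capsule` and, when both are given, by `curved_rod`.
#' @param inner_radius cavity radius of a `hollow_sphere` (mm).
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param padding_voxels background voxels added around the tight bounding
#'   box on every side.
#' @return A `shape_spec` object.
#' @seealso [make_shape()], [analytic_volume()]
#' @export
shape_spec <- function(kind = c("sphere", "capsule", "grooved_capsule",
                                "curved_rod", "hollow_sphere"),
                       radius, length = NULL, arc_radius = NULL,
                       groove_width = NULL, groove_depth = NULL,
                       inner_radius = NULL, voxel_size_mm,
                       padding_voxels = 2L) {
  kind <- match.arg(kind)
  h <- voxel_size_mm
  chk <- function(ok, msg) if (!isTRUE(ok)) acx_stop("invalid_shape_spec", msg)
  chk(is.numeric(h) && length(h) == 1 && is.finite(h) && h > 0,
      "voxel_size_mm must be a positive number")
  chk(is.numeric(radius) && length(radius) == 1 && is.finite(radius) && radius > 0,
      "radius must be strictly positive")
  chk(padding_voxels >= 0, "padding_voxels must be non-negative")
  chk(2 * radius >= 3 * h, "radius spans fewer than 3 voxels across")

  if (kind %in% c("capsule", "grooved_capsule", "curved_rod")) {
    chk(is.numeric(length) && length > 0, "length must be strictly positive")
  }
  if (kind == "curved_rod") {
    chk(is.numeric(arc_radius) && arc_radius > radius,
        "arc_radius must exceed the tube radius")
    chk(length / arc_radius <= pi,
        "arc angle (length/arc_radius) must not exceed pi")
  }
  grooved <- kind == "grooved_capsule" ||
    (kind == "curved_rod" && !is.null(groove_width) && !is.null(groove_depth))
  if (grooved) {
    chk(is.numeric(groove_width) && groove_width > 0 &&
        is.numeric(groove_depth) && groove_depth > 0,
        "groove_width and groove_depth must be strictly positive")
    chk(groove_depth < radius, "groove_depth must be smaller than radius")
    chk(groove_width >= 3 * h && groove_depth >= 3 * h,
        "groove dimensions span fewer than 3 voxels")
    # groove walls must stay inside the circular cross-section so the carved
    # prism has the closed-form area used by analytic_volume()
    chk(groove_width / 2 < sqrt(radius^2 - (radius - groove_depth)^2),
        "groove is wider than the chord at its floor depth")
  }
  if (kind == "hollow_sphere") {
    chk(is.numeric(inner_radius) && inner_radius > 0 && inner_radius < radius,
        "inner_radius must satisfy 0 < inner_radius < radius")
    chk(radius - inner_radius >= 3 * h,
        "shell thickness spans fewer than 3 voxels")
  }

  structure(list(kind = kind, radius = radius, length = length,
                 arc_radius = arc_radius, groove_width = groove_width,
                 groove_depth = groove_depth, inner_radius = inner_radius,
                 grooved = grooved, voxel_size_mm = h,
                 padding_voxels = as.integer(padding_voxels)),
            class = "shape_spec")
}

# closed-form cross-section area of the carved groove and the first moment of
# that area about the tube axis (used with Pappus' theorem for curved rods)
groove_section <- function(radius, w, d) {
  r <- radius
  area <- (w / 2) * sqrt(r^2 - w^2 / 4) + r^2 * asin(w / (2 * r)) - w * (r - d)
  moment <- ((r^2 - (r - d)^2) * w - w^3 / 12) / 2
  list(area = area, centroid = moment / area)
}

#' Analytic volume of a synthetic shape
#'
#' Closed-form volume of the solid described by a [shape_spec()]:
#' sphere \eqn{\frac{4}{3}\pi r^3}; capsule \eqn{\pi r^2 L + \frac{4}{3}\pi
#' r^3}; grooved capsule subtracts the groove prism (chord-segment area times
#' length); curved rod uses Pappus' theorem (cross-section area times the
#' path length of its centroid along the arc), with hemispherical end caps;
#' hollow sphere \eqn{\frac{4}{3}\pi(r_{out}^3 - r_{in}^3)}.
#'
#' @param spec a `shape_spec`.
#' @return Volume in mm^3.
#' @export
analytic_volume <- function(spec) {
  if (!inherits(spec, "shape_spec"))
    acx_stop("invalid_parameter", "spec must be a shape_spec")
  r <- spec$radius
  switch(spec$kind,
    sphere = 4 / 3 * pi * r^3,
    capsule = {
      v <- pi * r^2 * spec$length + 4 / 3 * pi * r^3
      v
    },
    grooved_capsule = {
      gs <- groove_section(r, spec$groove_width, spec$groove_depth)
      pi * r^2 * spec$length + 4 / 3 * pi * r^3 - gs$area * spec$length
    },
    curved_rod = {
      theta <- spec$length / spec$arc_radius
      v <- pi * r^2 * spec$length + 4 / 3 * pi * r^3   # Pappus: tube + caps
      if (spec$grooved) {
        gs <- groove_section(r, spec$groove_width, spec$groove_depth)
        # groove centroid rides outside the arc radius, so its swept length
        # is (arc_radius + centroid offset) * theta
        v <- v - gs$area * (spec$arc_radius + gs$centroid) * theta
      }
      v
    },
    hollow_sphere = 4 / 3 * pi * (r^3 - spec$inner_radius^3),
    acx_stop("unsupported", sprintf("no closed form for kind '%s'", spec$kind))
  )
}

# voxel-centre coordinate axes for a tight grid [lo, hi] plus padding
grid_axis <- function(lo, hi, h, pad) {
  n <- ceiling((hi - lo) / h - 1e-9) + 2 * pad
  start <- (lo + hi) / 2 - n * h / 2
  list(centres = start + (seq_len(n) - 0.5) * h, n = n)
}

#' Voxelise a synthetic shape
#'
#' Rasterises the analytic solid of a [shape_spec()] onto an isotropic voxel
#' grid: a voxel is foreground exactly when its centre lies inside the solid
#' (centre-inclusion, the semantics of a binarised CT scan).  The grid
#' tightly bounds the solid plus `padding_voxels`.  Deterministic: the same
#' spec always produces the identical volume.
#'
#' Axis convention matches [to_point_cloud()]: array dimensions are
#' (row = y, column = x, slice = z), and long axes of capsules lie along x.
#'
#' @param spec a `shape_spec`.
#' @return A [binary_volume()].
#' @examples
#' sp <- shape_spec("sphere", radius = 5, voxel_size_mm = 0.5)
#' vol <- make_shape(sp)
#' raw_volume(vol) / analytic_volume(sp)   # -> close to 1
#' @export
make_shape <- function(spec) {
  if (!inherits(spec, "shape_spec"))
    acx_stop("invalid_parameter", "spec must be a shape_spec")
  h <- spec$voxel_size_mm
  pad <- spec$padding_voxels
  r <- spec$radius

  bounds <- switch(spec$kind,
    sphere = list(x = c(-r, r), y = c(-r, r), z = c(-r, r)),
    capsule = ,
    grooved_capsule = {
      L2 <- spec$length / 2
      list(x = c(-L2 - r, L2 + r), y = c(-r, r), z = c(-r, r))
    },
    curved_rod = {
      R <- spec$arc_radius
      th2 <- spec$length / R / 2
      # arc in the x-y plane, centred on the origin, bulging towards +y
      xmax <- R * sin(th2) + r
      ymin <- R * cos(th2) - r
      ymax <- R + r
      list(x = c(-xmax, xmax), y = c(ymin, ymax), z = c(-r, r))
    },
    hollow_sphere = list(x = c(-r, r), y = c(-r, r), z = c(-r, r))
  )

  ax <- grid_axis(bounds$x[1], bounds$x[2], h, pad)
  ay <- grid_axis(bounds$y[1], bounds$y[2], h, pad)
  az <- grid_axis(bounds$z[1], bounds$z[2], h, pad)
  xs <- ax$centres; ys <- ay$centres; zs <- az$centres

  inside_slice <- function(z) {
    # matrix [row = y, col = x] of membership at slice height z
    X <- matrix(xs, nrow = ay$n, ncol = ax$n, byrow = TRUE)
    Y <- matrix(ys, nrow = ay$n, ncol = ax$n)
    switch(spec$kind,
      sphere = X^2 + Y^2 + z^2 <= r^2,
      capsule = {
        dx <- pmax(abs(X) - spec$length / 2, 0)
        dx^2 + Y^2 + z^2 <= r^2
      },
      grooved_capsule = {
        dx <- pmax(abs(X) - spec$length / 2, 0)
        memb <- dx^2 + Y^2 + z^2 <= r^2
        cut <- abs(X) <= spec$length / 2 &
               abs(z) <= spec$groove_width / 2 &
               Y >= r - spec$groove_depth
        memb & !cut
      },
      curved_rod = {
        R <- spec$arc_radius
        th2 <- spec$length / R / 2
        phi <- atan2(X, Y)
        phic <- pmin(pmax(phi, -th2), th2)
        axp <- R * sin(phic); ayp <- R * cos(phic)
        memb <- (X - axp)^2 + (Y - ayp)^2 + z^2 <= r^2
        if (spec$grooved) {
          radial <- sqrt(X^2 + Y^2) - R     # signed offset from the arc
          cut <- abs(phi) <= th2 &
                 abs(z) <= spec$groove_width / 2 &
                 radial >= r - spec$groove_depth
          memb <- memb & !cut
        }
        memb
      },
      hollow_sphere = {
        d2 <- X^2 + Y^2 + z^2
        d2 <= r^2 & d2 > spec$inner_radius^2
      }
    )
  }

  grid <- vapply(zs, inside_slice, matrix(TRUE, ay$n, ax$n))
  dim(grid) <- c(ay$n, ax$n, az$n)
  vol <- binary_volume(grid, h)
  attr(vol, "shape_spec") <- spec
  vol
}

#' Voxelised dumbbell: two disjoint balls
#'
#' Fixture for exercising component counting and alpha-shape breakdown: two
#' balls of radius `cluster_radius` whose centres sit `cluster_gap` apart
#' along the x axis.  The balls must be disjoint (`cluster_gap >
#' 2 * cluster_radius`).
#'
#' @param cluster_gap centre-to-centre distance (mm).
#' @param cluster_radius ball radius (mm).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param padding_voxels background padding per side.
#' @return A [binary_volume()] with exactly two connected components.
#' @export
make_dumbbell <- function(cluster_gap, cluster_radius, voxel_size_mm,
                          padding_voxels = 2L) {
  r <- cluster_radius; h <- voxel_size_mm
  if (!(is.numeric(cluster_gap) && cluster_gap > 2 * r))
    acx_stop("invalid_shape_spec",
             "clusters overlap: cluster_gap must exceed 2 * cluster_radius")
  if (h > r)
    acx_stop("invalid_shape_spec", "voxel size exceeds cluster_radius")
  if (2 * r < 3 * h)
    acx_stop("invalid_shape_spec", "cluster_radius spans fewer than 3 voxels")

  g2 <- cluster_gap / 2
  ax <- grid_axis(-g2 - r, g2 + r, h, padding_voxels)
  ay <- grid_axis(-r, r, h, padding_voxels)
  az <- grid_axis(-r, r, h, padding_voxels)
  xs <- ax$centres; ys <- ay$centres; zs <- az$centres
  grid <- vapply(zs, function(z) {
    X <- matrix(xs, nrow = ay$n, ncol = ax$n, byrow = TRUE)
    Y <- matrix(ys, nrow = ay$n, ncol = ax$n)
    (pmin((X - g2)^2, (X + g2)^2) + Y^2 + z^2) <= r^2
  }, matrix(TRUE, ay$n, ax$n))
  dim(grid) <- c(ay$n, ax$n, az$n)
  binary_volume(grid, h)
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s, radius %g mm, voxel %g mm%s\n", x$kind,
              x$radius, x$voxel_size_mm,
              if (isTRUE(x$grooved)) ", grooved" else ""))
  invisible(x)
}
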