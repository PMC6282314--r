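test_that("circumradius matches closed-form values and scales linearly", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))   # regular, edge 1
  expect_equal(circumradius(reg), sqrt(3 / 8), tolerance = 1e-12)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(circumradius(corner), sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(circumradius(corner * 3.7), 3.7 * sqrt(3) / 2,
               tolerance = 1e-12)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(circumradius(flat), class = "degenerate_input")
})

test_that("Delaunay handles minimal, degenerate and structured inputs", {
  four <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tri <- delaunay_tets(four)
  expect_identical(tri$n_tets, 1L)
  expect_equal(tri$volume, 1 / 6)

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tric <- delaunay_tets(cube)
  expect_equal(sum(tric$volume), 1, tolerance = 1e-12)

  coplanar <- cbind(matrix(runif(20, min = 0, max = 1), ncol = 2), 0)
  expect_error(delaunay_tets(coplanar), class = "degenerate_input")
})

test_that("alpha filtering keeps/drops the single regular tetrahedron correctly", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tri <- delaunay_tets(reg)
  kept <- alpha_complex(tri, 0.7)     # circumradius ~0.612 <= 0.7
  expect_equal(shape_volume(kept), sqrt(2) / 12, tolerance = 1e-12)
  expect_identical(count_components(kept), 1L)
  expect_identical(nrow(boundary_faces(kept)), 4L)

  dropped <- alpha_complex(tri, 0.5)
  expect_identical(shape_volume(dropped), 0)
  expect_identical(count_components(dropped), 0L)
  expect_identical(nrow(boundary_faces(dropped)), 0L)

  hull <- alpha_complex(tri, Inf)
  expect_equal(shape_volume(hull), convex_hull_volume(reg), tolerance = 1e-12)
})

test_that("boundary faces count faces of exactly one kept tet", {
  # two tets sharing a face -> 6 boundary triangles
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.4, 0.4, 1),
               c(0.4, 0.4, -1))
  tri <- delaunay_tets(pts)
  expect_identical(tri$n_tets, 2L)
  shp <- alpha_complex(tri, Inf)
  expect_identical(nrow(boundary_faces(shp)), 6L)
})

test_that("the alpha = infinity limit equals the independent convex hull", {
  for (seed in 1:5) {
    pts <- random_cloud(400, seed)
    tri <- delaunay_tets(pts)
    amax <- max(tri$circumradius[is.finite(tri$circumradius)])
    shp <- alpha_complex(tri, amax)
    expect_equal(shape_volume(shp), convex_hull_volume(pts),
                 tolerance = 1e-9)
  }
})

test_that("volume is monotone and kept sets nest across alphas", {
  b <- fixture_bundle("grooved", n = 3000, seed = 3)
  alphas <- alpha_from_k(build_grid(50)$values, b$l_ref)
  prev_kept <- integer(0)
  prev_vol <- 0
  for (a in alphas) {
    shp <- alpha_complex(b$tri, a)
    expect_true(all(prev_kept %in% shp$kept))
    expect_gte(shp$volume_mm3, prev_vol)
    prev_kept <- shp$kept
    prev_vol <- shp$volume_mm3
  }
})

test_that("boundary of a single-component shape is a closed surface", {
  b <- fixture_bundle("grooved", n = 3000, seed = 3)
  a <- alpha_from_k(10, b$l_ref)
  shp <- alpha_complex(b$tri, a)
  expect_identical(count_components(shp), 1L)
  f <- boundary_faces(shp)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2L))
  # outward winding: signed volume of the boundary mesh is positive and
  # equals the summed tet volume
  m <- surface_mesh(b$tri$points, f)
  expect_equal(mesh_volume(m), shape_volume(shp), tolerance = 1e-9)
})

test_that("alpha complexes match a brute-force oracle on small clouds", {
  for (cfg in list(list(n = 25, seed = 8), list(n = 40, seed = 9))) {
    pts <- random_cloud(cfg$n, cfg$seed)
    tri <- delaunay_tets(pts)
    bt <- oracle_delaunay(pts)
    got <- t(apply(tri$tets, 1, sort))
    expect_identical(nrow(got), nrow(bt$tets))
    o1 <- order(got[, 1], got[, 2], got[, 3], got[, 4])
    o2 <- order(bt$tets[, 1], bt$tets[, 2], bt$tets[, 3], bt$tets[, 4])
    expect_identical(got[o1, ], bt$tets[o2, , drop = FALSE])

    alphas <- seq(0.05, 0.9, length.out = 10)
    for (a in alphas) {
      shp <- alpha_complex(tri, a)
      ora <- oracle_alpha(bt, a)
      expect_equal(shape_volume(shp), ora$volume, tolerance = 1e-12)
      expect_identical(count_components(shp), ora$n_components)
      f <- boundary_faces(shp)
      keys <- if (nrow(f) == 0) character(0) else
        sort(apply(t(apply(f, 1, sort)), 1, paste, collapse = "-"))
      expect_identical(keys, ora$boundary_keys)
    }
  }
})

test_that("convex hull volume matches known solids and degenerates cleanly", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)
  four <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(four), 1 / 6, tolerance = 1e-12)
  # hull of points sampled inside a ball grows towards the ball volume
  vols <- vapply(c(100, 1000, 5000), function(n) {
    p <- random_cloud(n, 5) * 2 - 1
    p <- p[rowSums(p^2) <= 1, , drop = FALSE]
    convex_hull_volume(p)
  }, 0)
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 / 3 * pi))
  expect_error(convex_hull_volume(cbind(runif(10), runif(10), 1)),
               class = "degenerate_input")
})
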