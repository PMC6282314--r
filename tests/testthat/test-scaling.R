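test_that("reference lengths match hand-computed values", {
  expect_equal(ref_length_bbox(rbind(c(0, 0, 0), c(3, 4, 12)))$value_mm, 13)
  expect_equal(ref_length_centroid(rbind(c(-1, 0, 0), c(1, 0, 0)))$value_mm, 1)
  # collinear chain 0,1,2,3 with k = 2: per-point means (1.5, 1, 1, 1.5)
  chain <- cbind(0:3, 0, 0)
  expect_equal(ref_length_knn(chain, 2)$value_mm, 1.25)
  expect_equal(ref_length_knn(rbind(c(0, 0, 0), c(0, 0, 2.5)), 1)$value_mm, 2.5)
})

test_that("reference lengths are homogeneous of degree 1 and translation invariant", {
  pts <- random_cloud(300, 12)
  shift <- sweep(pts, 2, c(5, -2, 7), "+")
  for (f in list(ref_length_bbox, ref_length_centroid,
                 function(p) ref_length_knn(p, 20))) {
    expect_equal(f(pts * 2)$value_mm, 2 * f(pts)$value_mm, tolerance = 1e-12)
    expect_equal(f(shift)$value_mm, f(pts)$value_mm, tolerance = 1e-9)
  }
})

test_that("reference length rejects degenerate input", {
  expect_error(ref_length_bbox(rbind(c(1, 1, 1))), class = "invalid_parameter")
  expect_error(ref_length_bbox(rbind(c(1, 1, 1), c(1, 1, 1))),
               class = "invalid_parameter")     # zero extent
  expect_error(ref_length_knn(random_cloud(50, 1), 50),
               class = "invalid_parameter")
})

test_that("alpha scales linearly with k and rejects non-positive k", {
  expect_equal(alpha_from_k(2, 3), 6)
  lr <- ref_length_bbox(rbind(c(0, 0, 0), c(3, 4, 12)))
  expect_equal(alpha_from_k(1, lr), lr$value_mm)
  expect_error(alpha_from_k(0, 3), class = "invalid_parameter")
  expect_error(alpha_from_k(-1, lr), class = "invalid_parameter")
})

test_that("the refinement grid is log-uniform and endpoint-inclusive", {
  g <- build_grid(2)
  expect_equal(g$values, c(0.1, 10000))
  g3 <- build_grid(3, 1, 100)
  expect_equal(g3$values, c(1, 10, 100), tolerance = 1e-12)
  g200 <- build_grid()
  expect_identical(g200$n, 200L)
  expect_equal(range(g200$values), c(0.1, 10000), tolerance = 1e-12)
  ratios <- g200$values[-1] / g200$values[-200]
  expect_lt(diff(range(ratios)) / ratios[1], 1e-12)
  expect_error(build_grid(10, 5, 2), class = "invalid_parameter")
})

test_that("alpha curves are monotone, reach the hull, and flag breakdown", {
  b <- fixture_bundle("grooved", n = 5000, seed = 3)
  curve <- alpha_curve(b$pc, b$l_ref, b$raw, tri = b$tri)
  expect_false(is.unsorted(curve$volume_mm3))
  expect_equal(max(curve$volume_mm3), convex_hull_volume(b$pc),
               tolerance = 1e-9)
  expect_equal(curve$volume_pct_raw, 100 * curve$volume_mm3 / b$raw)
  kb <- breakdown_k(curve)
  expect_true(is.finite(kb))
  expect_true(all(curve$n_components[curve$k > kb] == 1L))
})

test_that("dumbbell clouds fragment into two clusters as k decreases", {
  db <- make_dumbbell(cluster_gap = 10, cluster_radius = 2,
                      voxel_size_mm = 0.25)
  pc <- downsample_cloud(to_point_cloud(db), 3000, seed = 6)
  lr <- ref_length_knn(pc, 100)
  tri <- delaunay_tets(pc)
  curve <- alpha_curve(pc, lr, raw_volume(db), tri = tri)
  expect_identical(curve$n_components[200], 1L)        # hull end
  expect_true(any(curve$n_components == 2L))
  # the two-ball stage must appear at coarser k than total fragmentation
  k_two <- max(curve$k[curve$n_components == 2L])
  expect_gt(k_two, max(curve$k[curve$n_components > 2L]))

  # geometric bounds on the breakdown alpha: a tet bridging the two balls
  # has circumradius at least (gap - 2r)/2; connectivity cannot persist
  # below that radius, and must persist at radii above the half-gap + r
  kb <- breakdown_k(curve)
  a_b <- alpha_from_k(kb, lr)
  expect_gte(a_b, (10 - 2 * 2) / 2 * 0.9)
  expect_lt(a_b, 10 / 2 + 2 * 2)
})

test_that("single-tetrahedron clouds never fragment on the grid", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tri <- delaunay_tets(reg)
  lr <- ref_length_bbox(reg)
  # restrict the grid to alphas at which the tet survives
  g <- build_grid(50, lo = 0.62 / lr$value_mm, hi = 100)
  curve <- alpha_curve(point_cloud(reg), lr, 0.1, grid = g, tri = tri)
  expect_true(all(curve$n_components == 1L))
  expect_true(is.na(breakdown_k(curve)))
})

test_that("optimal search hits the raw volume and agrees with bisection", {
  b <- fixture_bundle("grooved", n = 1e4, seed = 11)
  opt <- optimal_k(b$pc, b$l_ref, b$raw, tri = b$tri)
  expect_true(opt$converged)
  expect_lt(opt$rel_volume_mismatch, 1e-4)
  expect_equal(opt$volume_at_k_star, b$raw, tolerance = 2e-4)
  kb <- oracle_bisect_k(b$tri, b$l_ref, b$raw)
  expect_equal(opt$k_star, kb, tolerance = 0.01)
})

test_that("raw volumes beyond the hull raise no_crossing", {
  b <- fixture_bundle("grooved", n = 5000, seed = 3)
  hull <- convex_hull_volume(b$pc)
  expect_error(optimal_k(b$pc, b$l_ref, 2 * hull, tri = b$tri),
               class = "no_crossing")
})

test_that("coarsest-contribution labels distinguish hull, recessed and interior points", {
  # cube corners + strictly interior centre point
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)), c(0.5, 0.5, 0.5))
  tri <- delaunay_tets(pts)
  lr <- ref_length_bbox(pts)
  grid <- build_grid(50)
  cc <- coarsest_contribution(pts, lr, grid, tri = tri)
  expect_equal(cc$coarsest_k[1:8], rep(max(grid$values), 8))
  expect_true(is.na(cc$coarsest_k[9]))          # interior at every alpha

  # groove-floor points join the boundary only at finer refinement than
  # outer-surface points
  b <- fixture_bundle("grooved", n = 1e4, seed = 11)
  cc2 <- coarsest_contribution(b$pc, b$l_ref, tri = b$tri)
  sp <- b$spec
  co <- b$pc$coords
  ctr <- colMeans(co)
  x <- co[, 1] - ctr[1]; y <- co[, 2] - ctr[2]; z <- co[, 3] - ctr[3]
  h <- sp$voxel_size_mm
  floor_pts <- abs(x) < sp$length / 2 * 0.8 &
               abs(z) < sp$groove_width / 2 * 0.7 &
               y > (sp$radius - sp$groove_depth) - 2 * h &
               y < (sp$radius - sp$groove_depth) + h
  outer_pts <- y < -(sp$radius - 2 * h) & abs(x) < sp$length / 2 * 0.8
  expect_gt(sum(floor_pts), 20)
  expect_gt(sum(outer_pts), 20)
  expect_lt(median(cc2$coarsest_k[floor_pts], na.rm = TRUE),
            median(cc2$coarsest_k[outer_pts], na.rm = TRUE))
})
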