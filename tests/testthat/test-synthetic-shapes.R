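test_that("voxelised solids recover their analytic volumes", {
  # relative error of count * h^3 should be ~2% at r = 10 voxels and shrink
  # roughly in half when the voxel size is halved
  sp10 <- shape_spec("sphere", radius = 1, voxel_size_mm = 0.1)
  vol10 <- make_shape(sp10)
  expect_equal(sum(vol10), 4 / 3 * pi * 10^3, tolerance = 0.02)

  err <- vapply(c(0.1, 0.05), function(h) {
    sp <- shape_spec("sphere", radius = 1, voxel_size_mm = h)
    abs(raw_volume(make_shape(sp)) - analytic_volume(sp)) / analytic_volume(sp)
  }, 0)
  expect_lt(err[1], 0.02)
  expect_lt(err[2], err[1])

  for (which in c("capsule", "grooved_capsule", "curved_rod",
                  "curved_grooved", "hollow")) {
    sp <- switch(which,
      capsule = shape_spec("capsule", radius = 2, length = 8,
                           voxel_size_mm = 0.1),
      grooved_capsule = shape_spec("grooved_capsule", radius = 2, length = 8,
                                   groove_width = 1.2, groove_depth = 1,
                                   voxel_size_mm = 0.1),
      curved_rod = shape_spec("curved_rod", radius = 2, length = 8,
                              arc_radius = 6, voxel_size_mm = 0.1),
      curved_grooved = shape_spec("curved_rod", radius = 2, length = 8,
                                  arc_radius = 6, groove_width = 1.2,
                                  groove_depth = 1, voxel_size_mm = 0.1),
      hollow = shape_spec("hollow_sphere", radius = 2, inner_radius = 1,
                          voxel_size_mm = 0.1))
    expect_equal(raw_volume(make_shape(sp)), analytic_volume(sp),
                 tolerance = 0.02, label = which)
  }
})

test_that("closed-form volumes match their textbook values", {
  expect_equal(analytic_volume(shape_spec("sphere", radius = 1,
                                          voxel_size_mm = 0.1)),
               4 / 3 * pi)
  expect_equal(analytic_volume(shape_spec("capsule", radius = 1, length = 2,
                                          voxel_size_mm = 0.1)),
               2 * pi + 4 / 3 * pi)
  expect_equal(analytic_volume(shape_spec("hollow_sphere", radius = 2,
                                          inner_radius = 1,
                                          voxel_size_mm = 0.1)),
               4 / 3 * pi * 7)
  # ungrooved curved rod: Pappus tube + caps equals the straight capsule
  expect_equal(analytic_volume(shape_spec("curved_rod", radius = 1,
                                          length = 4, arc_radius = 4,
                                          voxel_size_mm = 0.1)),
               4 * pi + 4 / 3 * pi)
})

test_that("generators are deterministic and axis-symmetric", {
  sp <- shape_spec("sphere", radius = 1.05, voxel_size_mm = 0.1)
  a <- make_shape(sp)
  b <- make_shape(sp)
  expect_identical(grid_array(a), grid_array(b))
  g <- grid_array(a)
  expect_identical(g, aperm(g, c(2, 3, 1)))
  expect_identical(g, aperm(g, c(3, 1, 2)))
})

test_that("invalid shape specifications are rejected", {
  expect_error(shape_spec("sphere", radius = 0, voxel_size_mm = 0.1),
               class = "invalid_shape_spec")
  expect_error(shape_spec("sphere", radius = 0.1, voxel_size_mm = 0.1),
               class = "invalid_shape_spec")   # < 3 voxels across
  expect_error(shape_spec("grooved_capsule", radius = 2, length = 8,
                          groove_width = 1.2, groove_depth = 2.5,
                          voxel_size_mm = 0.1),
               class = "invalid_shape_spec")   # groove deeper than radius
  expect_error(shape_spec("hollow_sphere", radius = 1, inner_radius = 1.5,
                          voxel_size_mm = 0.05),
               class = "invalid_shape_spec")
  expect_error(shape_spec("curved_rod", radius = 2, length = 10,
                          arc_radius = 1.5, voxel_size_mm = 0.1),
               class = "invalid_shape_spec")   # arc tighter than the tube
})

test_that("dumbbell builds two components and rejects overlaps", {
  db <- make_dumbbell(cluster_gap = 10, cluster_radius = 2,
                      voxel_size_mm = 0.25)
  lab <- alphacomplexity:::cpp_label_components_3d(as.logical(db), dim(db))
  expect_identical(lab$n_components, 2L)
  expect_error(make_dumbbell(3, 2, 0.25), class = "invalid_shape_spec")
  expect_error(make_dumbbell(10, 2, 3), class = "invalid_shape_spec")
})
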