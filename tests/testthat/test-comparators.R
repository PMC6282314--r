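test_that("isosurface meshes are watertight, spherical-topology, and on budget", {
  ball <- make_shape(shape_spec("sphere", radius = 2, voxel_size_mm = 0.1))
  m <- mesh_surface(ball, target_faces = 10000L)
  expect_true(m$closed)
  expect_lt(abs(m$face_count - 10000) / 10000, 0.01)
  V <- nrow(m$vertices); FF <- m$face_count; E <- 3 * FF / 2
  expect_equal(V - E + FF, 2)                       # Euler characteristic
  expect_equal(mesh_volume(m), raw_volume(ball), tolerance = 0.02)
})

test_that("dissection index matches closed forms and is scale invariant", {
  # exact unit cube: 12 triangles over 8 corners
  cr <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  idx <- function(x, y, z) which(cr[, 1] == x & cr[, 2] == y & cr[, 3] == z)
  quads <- list(c(idx(0,0,0), idx(0,1,0), idx(1,1,0), idx(1,0,0)),  # z=0
                c(idx(0,0,1), idx(1,0,1), idx(1,1,1), idx(0,1,1)),  # z=1
                c(idx(0,0,0), idx(1,0,0), idx(1,0,1), idx(0,0,1)),  # y=0
                c(idx(0,1,0), idx(0,1,1), idx(1,1,1), idx(1,1,0)),  # y=1
                c(idx(0,0,0), idx(0,0,1), idx(0,1,1), idx(0,1,0)),  # x=0
                c(idx(1,0,0), idx(1,1,0), idx(1,1,1), idx(1,0,1)))  # x=1
  F <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  cube <- surface_mesh(cr, F)
  expect_true(cube$closed)
  expect_equal(abs(mesh_volume(cube)), 1, tolerance = 1e-12)
  expect_equal(dissection_index(cube), sqrt(6), tolerance = 1e-12)

  # refined icospheres approach the analytic sphere value from above
  di_exact <- sqrt(4 * pi) / (4 * pi / 3)^(1 / 3)
  dis <- vapply(1:3, function(s) dissection_index(oracle_icosphere(s)), 0)
  expect_true(all(diff(dis) < 0))
  expect_true(all(dis > di_exact))
  expect_equal(dis[3], di_exact, tolerance = 2e-3)

  big <- oracle_icosphere(2, radius = 7.3)
  expect_equal(dissection_index(big), dissection_index(oracle_icosphere(2)),
               tolerance = 1e-12)
})

test_that("non-watertight meshes are rejected", {
  tri1 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_false(tri1$closed)
  expect_error(dissection_index(tri1), class = "invalid_mesh")
})

test_that("box counts are exact on cubes, slabs and points", {
  cube <- binary_volume(array(TRUE, c(8, 8, 8)), 1)
  bc <- box_count(cube)
  expect_identical(bc$s, c(1L, 2L, 4L, 8L))
  expect_identical(bc$N, c(512L, 64L, 8L, 1L))

  slab <- array(FALSE, c(8, 8, 8)); slab[, , 1] <- TRUE
  bs <- box_count(binary_volume(slab, 1))
  expect_identical(bs$N, c(64L, 16L, 4L, 1L))

  one <- array(FALSE, c(8, 8, 8)); one[3, 5, 2] <- TRUE
  expect_identical(box_count(binary_volume(one, 1))$N, rep(1L, 4))
})

test_that("box counts agree with a naive triple-loop oracle", {
  withr::with_seed(31, {
    g <- array(runif(16^3) < 0.1, dim = c(16, 16, 16))
  })
  g[1, 1, 1] <- TRUE
  bc <- box_count(binary_volume(g, 1))
  for (row in seq_len(nrow(bc))) {
    s <- bc$s[row]
    cnt <- 0L
    for (i in seq(1, 16, by = s))
      for (j in seq(1, 16, by = s))
        for (k in seq(1, 16, by = s))
          if (any(g[i:(i + s - 1), j:(j + s - 1), k:(k + s - 1)])) cnt <- cnt + 1L
    expect_identical(bc$N[row], cnt)
  }
})

test_that("fractal dimension calibrates on solids, slabs and points", {
  cube <- binary_volume(array(TRUE, c(8, 8, 8)), 1)
  fd <- fractal_dimension(box_count(cube))
  expect_equal(fd$fd_slope, 3, tolerance = 1e-12)
  expect_equal(unname(fd$local_slopes), rep(3, 3), tolerance = 1e-12)
  expect_true(fd$plateau_detected)

  slab <- array(FALSE, c(8, 8, 8)); slab[, , 1] <- TRUE
  fd2 <- fractal_dimension(box_count(binary_volume(slab, 1)))
  expect_equal(fd2$fd_slope, 2, tolerance = 1e-12)
  expect_true(fd2$plateau_detected)

  one <- array(FALSE, c(8, 8, 8)); one[1, 1, 1] <- TRUE
  fd3 <- fractal_dimension(box_count(binary_volume(one, 1)))
  expect_equal(fd3$fd_slope, 0)

  expect_error(fractal_dimension(data.frame(s = c(1L, 2L), N = c(8L, 1L))),
               class = "invalid_parameter")
})

test_that("solid fixtures read as 3D and shells as 2D at adequate resolution", {
  # volume scaling emerges only when boxes are far below the object extent:
  # the surface term inflates N(s) by ~ 3s/(2r), so a 100-voxel radius keeps
  # the s <= 8 slopes above 2.9
  ball <- make_shape(shape_spec("sphere", radius = 2, voxel_size_mm = 0.02))
  fd <- fractal_dimension(box_count(ball), fit_range = c(1, 8))
  expect_gte(fd$fd_slope, 2.9)
  expect_lte(fd$fd_slope, 3.0)
  # a thin shell (3-voxel wall on a 32-voxel radius) reads as a surface
  shell <- make_shape(shape_spec("hollow_sphere", radius = 3.2,
                                 inner_radius = 2.9, voxel_size_mm = 0.1))
  fd2 <- fractal_dimension(box_count(shell))
  expect_gte(fd2$fd_slope, 1.9)
  expect_lte(fd2$fd_slope, 2.3)
})

test_that("DI of the sphere is the smallest among the phantom shapes", {
  shapes <- list(
    sphere = make_shape(shape_spec("sphere", radius = 2, voxel_size_mm = 0.1)),
    capsule = make_shape(shape_spec("capsule", radius = 2, length = 10,
                                    voxel_size_mm = 0.1)),
    grooved = fixture_bundle("grooved")$vol,
    curved = fixture_bundle("curved")$vol)
  di <- vapply(shapes, function(v) dissection_index(mesh_surface(v)), 0)
  expect_identical(names(which.min(di)), "sphere")
})
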