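test_that("binarize separates bimodal stacks and passes binary input through", {
  withr::with_seed(2, {
    stack <- array(rnorm(20^3, mean = 50, sd = 5), dim = c(20, 20, 20))
    fg <- array(FALSE, dim = dim(stack))
    fg[6:15, 6:15, 6:15] <- TRUE
    stack[fg] <- rnorm(sum(fg), mean = 200, sd = 5)
  })
  vol <- binarize(stack, voxel_size_mm = 0.5)
  expect_identical(grid_array(vol), fg)

  two <- array(0, dim = c(4, 4, 4)); two[2:3, 2:3, 2:3] <- 255
  vol2 <- binarize(two, 1)
  expect_identical(sum(vol2), 8L)

  expect_error(binarize(array(0, dim = c(4, 4, 4)), 1),
               class = "empty_foreground")
})

test_that("slice closing bridges contour gaps so cavities become fillable", {
  # annulus with a 4-px gap in one slice; unfilled until the gap is closed
  n <- 41
  xy <- expand.grid(r = 1:n, c = 1:n)
  d <- sqrt((xy$r - 21)^2 + (xy$c - 21)^2)
  ring <- matrix(d >= 10 & d <= 13, n, n)
  ring[19:22, 30:41] <- FALSE                   # breach the contour
  g <- array(FALSE, dim = c(n, n, 3))
  g[, , 2] <- ring
  vol <- binary_volume(g, 1)

  leaky <- fill_holes(vol)
  expect_identical(sum(leaky), sum(vol))        # cavity leaks: nothing filled

  closed <- close_slices(vol, 6L)
  filled <- fill_holes(closed)
  expect_gt(sum(filled), sum(closed) + 200)     # enclosed disc now filled

  solid <- fill_holes(binary_volume(array(TRUE, c(5, 5, 5)), 1))
  expect_identical(sum(solid), 125L)
  expect_identical(close_slices(vol, 0L), vol)
  expect_error(close_slices(vol, -1), class = "invalid_parameter")
})

test_that("hole filling turns a shell into the matching solid and is idempotent", {
  h <- 0.1
  shell <- make_shape(shape_spec("hollow_sphere", radius = 1.5,
                                 inner_radius = 1, voxel_size_mm = h))
  ball <- make_shape(shape_spec("sphere", radius = 1.5, voxel_size_mm = h))
  for (method in c("slice", "3d")) {
    filled <- fill_holes(shell, method)
    expect_identical(sum(filled), sum(ball), label = method)
    expect_identical(unclass(fill_holes(filled, method)), unclass(filled))
    expect_gte(sum(filled), sum(shell))
  }
  # C-shaped slice open to the image edge stays untouched
  cshape <- array(FALSE, dim = c(9, 9, 1))
  cshape[2:8, 2:3, 1] <- TRUE
  cshape[2:3, 2:8, 1] <- TRUE
  cshape[7:8, 2:8, 1] <- TRUE
  cv <- binary_volume(cshape, 1)
  expect_identical(sum(fill_holes(cv)), sum(cv))
})

test_that("raw volume is count times voxel size cubed", {
  g <- array(FALSE, dim = c(10, 10, 10)); g[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_equal(raw_volume(binary_volume(g, 0.05)), 1000 * 0.05^3)
  g1 <- array(FALSE, dim = c(1, 1, 1)); g1[1] <- TRUE
  expect_equal(raw_volume(binary_volume(g1, 1)), 1)
  expect_error(binary_volume(array(FALSE, c(2, 2, 2)), 1),
               class = "empty_foreground")
})

test_that("point clouds sit at voxel centres with interior points included", {
  g <- array(FALSE, dim = c(4, 4, 4)); g[1:2, 1:2, 1:2] <- TRUE
  pc <- to_point_cloud(binary_volume(g, 1))
  expect_identical(pc$n_points, 8L)
  expect_setequal(asplit(pc$coords, 1) |> lapply(paste, collapse = ",") |> unlist(),
                  apply(expand.grid(c(0.5, 1.5), c(0.5, 1.5), c(0.5, 1.5)),
                        1, paste, collapse = ","))
  g3 <- array(FALSE, dim = c(5, 5, 5)); g3[2:4, 2:4, 2:4] <- TRUE
  expect_identical(to_point_cloud(binary_volume(g3, 1))$n_points, 27L)
  g1 <- array(FALSE, dim = c(3, 3, 3)); g1[2, 2, 2] <- TRUE
  expect_identical(to_point_cloud(binary_volume(g1, 1))$n_points, 1L)
})

test_that("downsampling is seeded, identity at n = n_points, and bounded", {
  pc <- point_cloud(random_cloud(500, 4))
  a <- downsample_cloud(pc, 100, seed = 42)
  b <- downsample_cloud(pc, 100, seed = 42)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords,
                         downsample_cloud(pc, 100, seed = 43)$coords))
  full <- downsample_cloud(pc, 500, seed = 1)
  expect_setequal(full$coords[, 1], pc$coords[, 1])
  expect_error(downsample_cloud(pc, 501, seed = 1),
               class = "invalid_parameter")
  expect_error(downsample_cloud(pc, 3, seed = 1),
               class = "invalid_parameter")
})
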