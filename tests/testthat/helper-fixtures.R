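# Shared fixtures, built once per test run and cached.  The three "baculum
# analogue" fixtures mirror the morphologies the method is designed to rank:
# a smooth curved rod (coarse, ursid-like complexity), a straight capsule
# with a broad groove (canid-like), and a curved grooved rod (mustelid-like,
# most complex).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_spec <- function(which, voxel = 0.1) {
  switch(which,
    curved = shape_spec("curved_rod", radius = 2, length = 10, arc_radius = 6,
                        voxel_size_mm = voxel),
    grooved = shape_spec("grooved_capsule", radius = 2, length = 10,
                         groove_width = 1.2, groove_depth = 1,
                         voxel_size_mm = voxel),
    curved_grooved = shape_spec("curved_rod", radius = 2, length = 10,
                                arc_radius = 6, groove_width = 1.2,
                                groove_depth = 1, voxel_size_mm = voxel),
    sphere = shape_spec("sphere", radius = 2, voxel_size_mm = voxel),
    capsule = shape_spec("capsule", radius = 2, length = 10,
                         voxel_size_mm = voxel))
}

# volume + downsampled cloud + knn reference length + Delaunay, cached
fixture_bundle <- function(which, n = 1e4, seed = 11, voxel = 0.1) {
  cached(paste(which, n, seed, voxel, sep = "_"), {
    sp <- fixture_spec(which, voxel)
    vol <- make_shape(sp)
    pc_full <- to_point_cloud(vol)
    pc <- if (pc_full$n_points > n) downsample_cloud(pc_full, n, seed) else pc_full
    tri <- delaunay_tets(pc)
    list(spec = sp, vol = vol, raw = raw_volume(vol), pc = pc,
         l_ref = ref_length_knn(pc, 100), tri = tri)
  })
}

random_cloud <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(3 * n), ncol = 3))
}

# bare logical array, attributes stripped, for grid comparisons
grid_array <- function(v) array(as.logical(v), dim(v))
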