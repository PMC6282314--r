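# Batch orchestration: per-specimen end-to-end processing, multi-specimen
# summary tables, and the point-cloud-density sensitivity sweep.

#' Run configuration
#'
#' Bundles every tunable of the pipeline with the package defaults: closing
#' disc radius 6 px, slice-wise hole filling, downsampling to 100,000
#' points, knn reference length with 100 neighbours, a 200-point refinement
#' grid on [0.1, 10,000], stopping tolerance 1e-4, and 10,000-face
#' comparator meshes.  When `out_dir` is set the resolved configuration is
#' written next to the outputs so every reported number is traceable to a
#' config and a seed.
#'
#' @param seed integer seed for every stochastic step (downsampling).
#' @param closing_radius_px disc radius for [close_slices()].
#' @param fill_method `"slice"` or `"3d"` (see [fill_holes()]).
#' @param downsample_n point-cloud size after downsampling.
#' @param ref_method `"knn_mean"`, `"centroid_mean"` or `"bbox_diagonal"`.
#' @param k_neighbors neighbour count for the knn reference length.
#' @param grid_n,grid_lo,grid_hi refinement grid (see [build_grid()]).
#' @param tol optimal-search stopping tolerance.
#' @param target_faces comparator mesh face budget.
#' @param smooth_iterations Taubin iterations before decimation.
#' @param metrics character subset of `c("alpha", "di", "fd")`.
#' @param min_feature_mm smallest feature of interest; a warning is emitted
#'   if downsampling leaves fewer than ~3 points across it.
#' @param out_dir output directory (`NULL` = no files written).
#' @param write_meshes also export alpha-shape meshes at the convex hull,
#'   an intermediate refinement, the optimum and past breakdown.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, closing_radius_px = 6L, fill_method = "slice",
                       downsample_n = 1e5, ref_method = "knn_mean",
                       k_neighbors = 100L, grid_n = 200L, grid_lo = 0.1,
                       grid_hi = 10000, tol = 1e-4, target_faces = 10000L,
                       smooth_iterations = 10L,
                       metrics = c("alpha", "di", "fd"),
                       min_feature_mm = NULL, out_dir = NULL,
                       write_meshes = FALSE) {
  if (missing(seed)) acx_stop("invalid_parameter", "a seed is required")
  structure(list(seed = as.integer(seed),
                 closing_radius_px = closing_radius_px,
                 fill_method = fill_method, downsample_n = downsample_n,
                 ref_method = ref_method, k_neighbors = k_neighbors,
                 grid_n = grid_n, grid_lo = grid_lo, grid_hi = grid_hi,
                 tol = tol, target_faces = target_faces,
                 smooth_iterations = smooth_iterations, metrics = metrics,
                 min_feature_mm = min_feature_mm, out_dir = out_dir,
                 write_meshes = write_meshes),
            class = "run_config")
}

reference_length_for <- function(pc, config) {
  switch(config$ref_method,
    knn_mean = ref_length_knn(pc, config$k_neighbors),
    centroid_mean = ref_length_centroid(pc),
    bbox_diagonal = ref_length_bbox(pc),
    acx_stop("invalid_parameter",
             sprintf("unknown ref_method '%s'", config$ref_method)))
}

load_input <- function(input, config, voxel_size_mm = NULL) {
  if (inherits(input, "binary_volume")) return(input)
  if (is.character(input)) {
    ext <- tolower(tools::file_ext(input))
    arr <- if (ext %in% c("tif", "tiff")) read_ct_tiff(input)
           else read_ct_raw(input)
    vs <- attr(arr, "voxel_size_mm") %||% voxel_size_mm
    if (is.null(vs))
      acx_stop("invalid_parameter", "voxel size unknown: supply voxel_size_mm")
    return(binarize(arr, vs))
  }
  if (is.array(input)) {
    if (is.null(voxel_size_mm))
      acx_stop("invalid_parameter", "voxel_size_mm is required for array input")
    return(binarize(input, voxel_size_mm))
  }
  acx_stop("invalid_parameter", "unsupported input type")
}

#' Process one specimen end to end
#'
#' Runs the full pipeline: binarise (if needed), slice closing, hole
#' filling, raw volume, point cloud, downsampling, reference length, alpha
#' curve, optimal refinement search, breakdown detection, and the comparator
#' metrics enabled in the config.  When `out_dir` is set, writes the
#' per-specimen JSON report, the alpha-curve CSV, a summary CSV row, and
#' (optionally) alpha-shape meshes at the hull, an intermediate refinement,
#' the optimum and past breakdown.
#'
#' A `no_crossing` condition from the optimal search (raw volume above hull
#' volume, the signature of a convex segmentation) is caught and recorded as
#' the failure reason; the rest of the report is still produced.
#'
#' @param input a [binary_volume()], grayscale array, or a stack path
#'   (TIFF, or raw with JSON sidecar).
#' @param config a [run_config()].
#' @param id specimen identifier.
#' @param voxel_size_mm voxel size for array input.
#' @return A `complexity_report`.
#' @export
process_specimen <- function(input, config, id = "specimen",
                             voxel_size_mm = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  vol <- load_input(input, config, voxel_size_mm)
  vol <- close_slices(vol, config$closing_radius_px)
  vol <- fill_holes(vol, config$fill_method)
  rv <- raw_volume(vol)
  pc_full <- to_point_cloud(vol)
  pc <- if (pc_full$n_points > config$downsample_n)
    downsample_cloud(pc_full, config$downsample_n, config$seed) else pc_full
  timings["preprocess_s"] <- tic() - t0

  if (!is.null(config$min_feature_mm)) {
    # rule of thumb: the smallest feature should span >= 3-4 points
    spacing <- (rv / pc$n_points)^(1 / 3)
    if (config$min_feature_mm < 3 * spacing)
      warning(sprintf(
        "specimen %s: features of %g mm span fewer than ~3 points at this density",
        id, config$min_feature_mm), call. = FALSE)
  }

  t0 <- tic()
  l_ref <- reference_length_for(pc, config)
  timings["ref_length_s"] <- tic() - t0

  t0 <- tic()
  tri <- delaunay_tets(pc)
  grid <- build_grid(config$grid_n, config$grid_lo, config$grid_hi)
  curve <- alpha_curve(pc, l_ref, rv, grid, tri = tri, specimen_id = id)
  kb <- breakdown_k(curve)
  opt <- NULL
  failure <- NULL
  if ("alpha" %in% config$metrics) {
    opt <- tryCatch(
      optimal_k(pc, l_ref, rv, tol = config$tol, grid = grid, tri = tri),
      no_crossing = function(e) { failure <<- conditionMessage(e); NULL })
  }
  timings["alpha_s"] <- tic() - t0

  di <- fd <- NULL
  if ("di" %in% config$metrics) {
    t0 <- tic()
    mesh <- mesh_surface(vol, config$target_faces, config$smooth_iterations)
    di <- dissection_index(mesh)
    timings["di_s"] <- tic() - t0
  }
  if ("fd" %in% config$metrics) {
    t0 <- tic()
    fd <- fractal_dimension(box_count(vol))
    timings["fd_s"] <- tic() - t0
  }

  report <- structure(list(
    id = id, raw_volume_mm3 = rv, n_points = pc$n_points,
    seed = config$seed, l_ref = l_ref,
    k_star = if (!is.null(opt)) opt$k_star else NA_real_,
    converged = if (!is.null(opt)) opt$converged else FALSE,
    rel_volume_mismatch = if (!is.null(opt)) opt$rel_volume_mismatch else NA_real_,
    breakdown_k = kb,
    dissection_index = if (!is.null(di)) di else NA_real_,
    fractal_dimension = if (!is.null(fd)) fd$fd_slope else NA_real_,
    fd_plateau = if (!is.null(fd)) fd$plateau_detected else NA,
    failure = failure, curve = curve, timings = timings),
    class = "complexity_report")

  if (!is.null(config$out_dir)) write_report(report, vol, tri, config, grid)
  report
}

summary_row <- function(r) {
  data.frame(specimen_id = r$id, raw_volume_mm3 = r$raw_volume_mm3,
             n_points = r$n_points, seed = r$seed,
             l_ref_mm = r$l_ref$value_mm, l_ref_method = r$l_ref$method,
             k_star = r$k_star, converged = r$converged,
             breakdown_k = r$breakdown_k,
             dissection_index = r$dissection_index,
             fractal_dimension = r$fractal_dimension,
             fd_plateau = r$fd_plateau,
             failure = if (is.null(r$failure)) "" else r$failure)
}

write_report <- function(report, vol, tri, config, grid) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, report$id)
  write_curve_csv(report$curve, paste0(base, "_curve.csv"))
  utils::write.csv(summary_row(report), paste0(base, "_summary.csv"),
                   row.names = FALSE)
  rep2 <- report
  rep2$curve <- NULL
  jsonlite::write_json(rep2, paste0(base, "_report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), paste0(base, "_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (isTRUE(config$write_meshes) && !is.na(report$k_star)) {
    l_ref <- report$l_ref
    kb <- report$breakdown_k
    stages <- c(hull = Inf,
                intermediate = sqrt(report$k_star * config$grid_hi),
                optimal = report$k_star,
                broken = if (!is.na(kb)) kb * 0.9 else NA)
    for (nm in names(stages)) {
      kk <- stages[[nm]]
      if (is.na(kk)) next
      a <- if (is.infinite(kk)) Inf else alpha_from_k(kk, l_ref)
      shp <- alpha_complex(tri, a, k = kk)
      m <- surface_mesh(tri$points, boundary_faces(shp))
      write_ply_mesh(m, paste0(base, "_alpha_", nm, ".ply"),
                     comment = sprintf("specimen %s alpha %.6g mm k %.6g",
                                       report$id, a, kk))
    }
  }
  invisible(report)
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s\n", x$id))
  cat(sprintf("  raw volume   %.6g mm^3 (%d points, seed %d)\n",
              x$raw_volume_mm3, x$n_points, x$seed))
  cat(sprintf("  l_ref        %.6g mm (%s)\n", x$l_ref$value_mm, x$l_ref$method))
  if (!is.na(x$k_star))
    cat(sprintf("  optimal k*   %.6g (%s)\n", x$k_star,
                if (x$converged) "converged" else "not converged"))
  else
    cat(sprintf("  optimal k*   unavailable (%s)\n", x$failure %||% "disabled"))
  cat(sprintf("  breakdown k  %.4g\n", x$breakdown_k))
  if (!is.na(x$dissection_index))
    cat(sprintf("  DI           %.4f\n", x$dissection_index))
  if (!is.na(x$fractal_dimension))
    cat(sprintf("  FD           %.4f (plateau %s)\n", x$fractal_dimension,
                if (isTRUE(x$fd_plateau)) "detected" else "absent"))
  invisible(x)
}

#' Process a batch of specimens
#'
#' Applies [process_specimen()] to each input; failures are caught, logged
#' and reported, and the remaining specimens still complete.  When
#' `out_dir` is set a combined `summary.csv` is written.
#'
#' @param inputs named list of inputs (see [process_specimen()]).
#' @param config a [run_config()].
#' @param voxel_size_mm voxel size for array inputs.
#' @return List with `reports` (one per successful specimen), `summary`
#'   (data.frame), `failed` (named character vector of error messages).
#' @export
process_batch <- function(inputs, config, voxel_size_mm = NULL) {
  ids <- names(inputs) %||% paste0("specimen_", seq_along(inputs))
  reports <- list()
  failed <- character(0)
  for (i in seq_along(inputs)) {
    r <- tryCatch(process_specimen(inputs[[i]], config, id = ids[i],
                                   voxel_size_mm = voxel_size_mm),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failed[ids[i]] <- conditionMessage(r)
      message(sprintf("specimen %s failed: %s", ids[i], conditionMessage(r)))
    } else reports[[ids[i]]] <- r
  }
  summary <- do.call(rbind, lapply(reports, summary_row))
  if (!is.null(config$out_dir) && length(reports)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(reports = reports, summary = summary, failed = failed)
}

#' Sensitivity of the optimal refinement to point-cloud density
#'
#' Recomputes `k*` across a range of point-cloud sizes.  Subsampling is
#' nested (every smaller cloud is a subset of the next larger one, drawn
#' from one seeded permutation) so that the density effect is not
#' confounded with independent resampling noise, and the reference length
#' is computed once, from the smallest cloud, and reused for every size --
#' this keeps the alpha radii identical across sizes so the runs are
#' directly comparable.  Because coarser clouds lose outer-contour points
#' ('coastline paradox'), `k*` is expected to decrease as size grows.
#'
#' @param input a [binary_volume()] or a [point_cloud()] (full resolution).
#' @param config a [run_config()].
#' @param sizes point-cloud sizes, ascending (default `10^4` and `10^5`).
#' @param raw_volume_mm3 required when `input` is a point cloud.
#' @return Data frame with `size`, `k_star`, `converged`, `seconds`.
#' @export
sensitivity_sweep <- function(input, config, sizes = c(1e4, 1e5),
                              raw_volume_mm3 = NULL) {
  stopifnot(inherits(config, "run_config"))
  sizes <- sort(as.integer(sizes))
  if (inherits(input, "binary_volume")) {
    raw_volume_mm3 <- raw_volume(input)
    pc_full <- to_point_cloud(input)
  } else if (inherits(input, "point_cloud")) {
    if (is.null(raw_volume_mm3))
      acx_stop("invalid_parameter",
               "raw_volume_mm3 is required for point-cloud input")
    pc_full <- input
  } else acx_stop("invalid_parameter", "unsupported input type")
  if (max(sizes) > pc_full$n_points)
    acx_stop("invalid_parameter", sprintf(
      "largest size (%d) exceeds available points (%d)", max(sizes),
      pc_full$n_points))

  perm <- withr::with_seed(config$seed, sample.int(pc_full$n_points))
  clouds <- lapply(sizes, function(n)
    point_cloud(pc_full$coords[perm[seq_len(n)], , drop = FALSE],
                voxel_size_mm = pc_full$voxel_size_mm, seed = config$seed))
  l_ref <- reference_length_for(clouds[[1]], config)   # fixed from smallest
  grid <- build_grid(config$grid_n, config$grid_lo, config$grid_hi)

  rows <- lapply(seq_along(sizes), function(i) {
    t0 <- proc.time()[["elapsed"]]
    opt <- optimal_k(clouds[[i]], l_ref, raw_volume_mm3, tol = config$tol,
                     grid = grid)
    data.frame(size = sizes[i], k_star = opt$k_star,
               converged = opt$converged,
               seconds = proc.time()[["elapsed"]] - t0)
  })
  do.call(rbind, rows)
}
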