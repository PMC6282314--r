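# File I/O: CT stacks (multi-page TIFF; headerless raw + JSON sidecar),
# point clouds (XYZ text, PLY) and surface meshes (PLY/OFF/STL, ASCII).

#' Read a CT stack
#'
#' `read_ct_tiff()` reads a multi-page TIFF into a numeric array (row,
#' column, slice), rescaling to the native integer range.
#' `read_ct_raw()` reads a headerless raw volume with a JSON sidecar
#' giving `nx`, `ny`, `nz`, `voxel_size_mm`, `dtype` ("uint8" or "uint16")
#' and optionally `byte_order` ("little"/"big").
#'
#' @param path file path.
#' @return A numeric 3D array with attribute `voxel_size_mm` when known.
#' @name ct_readers
NULL

#' @rdname ct_readers
#' @export
read_ct_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' @rdname ct_readers
#' @param meta sidecar path (default: `path` with a `.json` extension) or a
#'   named list.
#' @export
read_ct_raw <- function(path, meta = NULL) {
  if (is.null(meta))
    meta <- paste0(tools::file_path_sans_ext(path), ".json")
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  need <- c("nx", "ny", "nz", "voxel_size_mm", "dtype")
  if (!all(need %in% names(meta)))
    acx_stop("invalid_parameter", paste("sidecar metadata must contain:",
                                        paste(need, collapse = ", ")))
  size <- switch(meta$dtype, uint8 = 1L, uint16 = 2L,
                 acx_stop("unsupported", "dtype must be uint8 or uint16"))
  endian <- switch(meta$byte_order %||% "little", little = "little",
                   big = "big")
  n <- meta$nx * meta$ny * meta$nz
  v <- readBin(path, what = "integer", n = n, size = size, signed = FALSE,
               endian = endian)
  if (length(v) != n)
    acx_stop("invalid_parameter", "raw file shorter than nx*ny*nz voxels")
  arr <- array(as.numeric(v), dim = c(meta$ny, meta$nx, meta$nz))
  attr(arr, "voxel_size_mm") <- meta$voxel_size_mm
  arr
}

#' Write a binarised stack as multi-page TIFF
#'
#' @param vol a [binary_volume()].
#' @param path output file.
#' @export
write_binary_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "binary_volume"))
  slices <- lapply(seq_len(dim(vol)[3]), function(s) (vol[, , s]) * 1)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' Point-cloud text I/O
#'
#' Plain XYZ text: one `x y z` triple per line.
#'
#' @param pc a [point_cloud()].
#' @param path file path.
#' @name xyz_io
NULL

#' @rdname xyz_io
#' @export
write_xyz <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  utils::write.table(format(pc$coords, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname xyz_io
#' @export
read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  point_cloud(m)
}

#' Write a point cloud as ASCII PLY
#'
#' Optionally attaches one scalar property per vertex (e.g. the
#' coarsest-contribution label from [coarsest_contribution()]).
#'
#' @param pc a [point_cloud()].
#' @param path output file.
#' @param scalar optional numeric vector, one value per point.
#' @param scalar_name PLY property name for `scalar`.
#' @param comment provenance comment embedded in the header.
#' @export
write_ply_points <- function(pc, path, scalar = NULL,
                             scalar_name = "coarsest_k", comment = NULL) {
  stopifnot(inherits(pc, "point_cloud"))
  n <- pc$n_points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               if (!is.null(comment)) paste("comment", comment),
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               if (!is.null(scalar)) sprintf("property double %s", scalar_name),
               "end_header"), con)
  dat <- pc$coords
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    dat <- cbind(dat, scalar)
  }
  utils::write.table(format(dat, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mesh writers (ASCII PLY / OFF / STL)
#'
#' @param mesh a [surface_mesh()] (or any list with `vertices` and `faces`).
#' @param path output file.
#' @param comment provenance comment (PLY and OFF; e.g. specimen id, alpha,
#'   k).
#' @name mesh_writers
NULL

#' @rdname mesh_writers
#' @export
write_ply_mesh <- function(mesh, path, comment = NULL) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               if (!is.null(comment)) paste("comment", comment),
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(V, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, F - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_writers
#' @export
write_off_mesh <- function(mesh, path, comment = NULL) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", if (!is.null(comment)) paste("#", comment),
               sprintf("%d %d 0", nrow(V), nrow(F))), con)
  utils::write.table(format(V, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, F - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_writers
#' @export
write_stl_mesh <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c <- V[F[i, 3], ]
    u <- b - a; v <- c - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                 "  outer loop",
                 sprintf("    vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
                 sprintf("    vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
                 sprintf("    vertex %.17g %.17g %.17g", c[1], c[2], c[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

#' Mesh readers (ASCII PLY / OFF)
#'
#' Minimal readers for the ASCII meshes this package writes.
#'
#' @param path file path.
#' @return A [surface_mesh()].
#' @name mesh_readers
NULL

#' @rdname mesh_readers
#' @export
read_off_mesh <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!grepl("^OFF", ln[1])) acx_stop("invalid_mesh", "not an OFF file")
  hdr <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  V <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  F <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  surface_mesh(V, F)
}

#' @rdname mesh_readers
#' @export
read_ply_mesh <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "ply" || !any(grepl("format ascii", ln)))
    acx_stop("invalid_mesh", "only ASCII PLY is supported")
  endh <- which(ln == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   ln[1:endh], value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 ln[1:endh], value = TRUE)))
  V <- do.call(rbind, lapply(ln[(endh + 1):(endh + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  F <- do.call(rbind, lapply(ln[(endh + nv + 1):(endh + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  surface_mesh(V, F)
}

#' Write an alpha curve as CSV
#'
#' Columns: `specimen_id`, `k`, `alpha_mm`, `volume_mm3`, `volume_pct_raw`,
#' `n_components`.
#'
#' @param curve an [alpha_curve()] result.
#' @param path output file.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "alpha_curve"))
  df <- cbind(specimen_id = attr(curve, "specimen_id"), as.data.frame(curve))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
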