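#' Triangulated surface mesh
#'
#' Lightweight triangle-soup container: `vertices` is an `n x 3` matrix of
#' coordinates (mm) and `faces` an `m x 3` matrix of 1-based vertex indices.
#'
#' @param vertices Numeric `n x 3` matrix.
#' @param faces Integer `m x 3` matrix of vertex indices.
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    abort("face indices out of range", class = "tpmsdesign_invalid_mesh")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total area of a triangle mesh
#'
#' @param mesh A [surface_mesh()].
#' @return Total triangle area (mm^2).
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sum(sqrt(rowSums(cr^2)))
}

#' Extract the zero isosurface of a sampled scalar field
#'
#' Runs marching tetrahedra on a regular grid of field samples. The solid
#' convention is `field > 0` inside; the returned mesh triangulates the
#' `field = 0` level set with linear interpolation along tetrahedron edges.
#'
#' @param field Numeric 3-D array of field samples at grid nodes.
#' @param spacing Node spacing (mm).
#' @param origin Coordinates of node `[1, 1, 1]` (mm).
#' @return A [surface_mesh()].
#' @export
isosurface <- function(field, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(field)) == 3, spacing > 0)
  res <- .march_tetra(as.numeric(field), as.integer(dim(field)),
                      as.numeric(origin), spacing)
  surface_mesh(res$vertices, res$faces)
}

# Signed solid field of a design at grid nodes: positive inside the shell
# solid, intersected with the cylindrical envelope via pointwise min of the
# shell band (t/2 - metric distance) and the envelope's signed distances.
solid_field <- function(design, pts) {
  band <- if (design$full_solid) {
    rep(design$diameter, nrow(pts)) # any positive value
  } else {
    design$thickness / 2 - surface_distance(design, pts)
  }
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  pmin(band, design$diameter / 2 - r, pts[, 3], design$height - pts[, 3])
}

#' Extract the boundary surface of a lattice solid
#'
#' Samples the shell solid's signed field (positive inside) on a node grid
#' padded by one spacing beyond the envelope, and triangulates its zero
#' level set. The mesh therefore includes the cylindrical and planar cut
#' faces of the clipped shell, not just the TPMS sheet faces.
#'
#' @inheritParams voxelize
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(design, spacing, max_cells = 2.5e7) {
  stopifnot(spacing > 0)
  D <- design$diameter; H <- design$height
  nx <- ceiling(D / spacing) + 3L; ny <- nx
  nz <- ceiling(H / spacing) + 3L
  if (as.double(nx) * ny * nz > max_cells) {
    abort(sprintf("node grid of %.3g cells exceeds budget %.3g; increase spacing",
                  as.double(nx) * ny * nz, max_cells),
          class = "tpmsdesign_resolution_error")
  }
  origin <- c(-(nx - 1) * spacing / 2, -(ny - 1) * spacing / 2,
              -spacing * 1.5 + 0 * H)
  xs <- origin[1] + (seq_len(nx) - 1) * spacing
  ys <- origin[2] + (seq_len(ny) - 1) * spacing
  zs <- origin[3] + (seq_len(nz) - 1) * spacing
  fld <- array(NA_real_, dim = c(nx, ny, nz))
  xy <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  chunk <- max(1L, floor(2e6 / nrow(xy)))
  for (z0 in seq(1L, nz, by = chunk)) {
    z1 <- min(nz, z0 + chunk - 1L)
    pts <- cbind(xy[rep(seq_len(nrow(xy)), z1 - z0 + 1L), , drop = FALSE],
                 rep(zs[z0:z1], each = nrow(xy)))
    fld[, , z0:z1] <- solid_field(design, pts)
  }
  mesh <- isosurface(fld, spacing, origin)
  if (nrow(mesh$faces) == 0) {
    abort("empty solid: no isosurface found (thickness or envelope too small for this spacing)",
          class = "tpmsdesign_empty_mesh")
  }
  mesh
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL in mm: 80-byte header, `uint32` triangle count,
#' then 50 bytes per triangle (normal, three vertices as `float32`, and a
#' zero attribute word).
#'
#' @param mesh A non-empty [surface_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  if (nrow(mesh$faces) == 0) {
    abort("refusing to write an empty mesh", class = "tpmsdesign_empty_mesh")
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(paste0("cannot open '", path, "': ",
                                                   conditionMessage(e))))
  on.exit(close(con))
  header <- charToRaw(formatC("tpmsdesign binary STL (mm)", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats per triangle: normal, then the three vertices
  block <- t(cbind(nrm, a, b, c_))
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Minimal reader for the format written by [write_stl()]; used mainly for
#' round-trip verification.
#'
#' @param path Path to a binary STL file.
#' @return A [surface_mesh()] (triangle soup).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  verts <- matrix(NA_real_, nrow = 3 * nf, ncol = 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    invisible(readBin(con, "integer", n = 1, size = 2, endian = "little"))
    verts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], nrow = 3, byrow = TRUE)
  }
  surface_mesh(verts, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}
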