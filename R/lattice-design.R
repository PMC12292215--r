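#' Construct a lattice design point
#'
#' A design point holds the seven geometric parameters of a cylindrical
#' shell-type TPMS lattice: surface family, per-axis unit-cell size, shell
#' thickness, rotation angle about the X axis, and the height and diameter
#' of the cylindrical envelope.
#'
#' @param surface_type One of [tpms_surfaces()].
#' @param cell_size_x,cell_size_y,cell_size_z Unit-cell sizes (mm), > 0.
#' @param thickness Shell thickness (mm), > 0 and below the smallest cell
#'   size (unless `full_solid = TRUE`).
#' @param rotation_deg Rotation about the X axis, in `[0, 90)` degrees.
#' @param height,diameter Cylindrical envelope dimensions (mm), > 0.
#' @param full_solid Degenerate override used for testing: treat every point
#'   inside the envelope as solid regardless of the field.
#' @return An object of class `lattice_design`.
#' @examples
#' lattice_design("gyroid", 3, 3, 4, thickness = 0.3, rotation_deg = 60,
#'                height = 8, diameter = 5)
#' @export
lattice_design <- function(surface_type, cell_size_x, cell_size_y, cell_size_z,
                           thickness, rotation_deg = 0, height, diameter,
                           full_solid = FALSE) {
  surface_type <- match.arg(surface_type, tpms_surfaces())
  lengths <- c(cell_size_x = cell_size_x, cell_size_y = cell_size_y,
               cell_size_z = cell_size_z, thickness = thickness,
               height = height, diameter = diameter)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("all lengths must be finite and positive",
          class = "tpmsdesign_invalid_design")
  }
  if (!full_solid && thickness >= min(cell_size_x, cell_size_y, cell_size_z)) {
    abort("thickness must be smaller than the smallest cell size (or set full_solid = TRUE)",
          class = "tpmsdesign_invalid_design")
  }
  if (rotation_deg < 0 || rotation_deg >= 90) {
    abort("rotation_deg must lie in [0, 90)",
          class = "tpmsdesign_invalid_design")
  }
  structure(
    list(surface_type = surface_type,
         cell_size_x = cell_size_x, cell_size_y = cell_size_y,
         cell_size_z = cell_size_z, thickness = thickness,
         rotation_deg = rotation_deg, height = height, diameter = diameter,
         full_solid = isTRUE(full_solid)),
    class = "lattice_design"
  )
}

#' @export
print.lattice_design <- function(x, ...) {
  cat(sprintf(
    "<lattice_design> %s | cells %.3g x %.3g x %.3g mm | t %.3g mm | rot %g deg | H %.3g mm, D %.3g mm%s\n",
    x$surface_type, x$cell_size_x, x$cell_size_y, x$cell_size_z,
    x$thickness, x$rotation_deg, x$height, x$diameter,
    if (x$full_solid) " [full solid]" else ""))
  invisible(x)
}

#' Coerce a one-row data frame to a lattice design
#'
#' Accepts the column layout produced by [enumerate_designs()]:
#' `surface_type`, `cell_size_x/y/z`, `thickness`, `rotation_deg`,
#' `height`, `diameter`.
#'
#' @param row A one-row data frame.
#' @return A `lattice_design`.
#' @export
as_lattice_design <- function(row) {
  stopifnot(nrow(row) == 1)
  full_solid <- "full_solid" %in% names(row) && isTRUE(row$full_solid)
  lattice_design(row$surface_type, row$cell_size_x, row$cell_size_y,
                 row$cell_size_z, row$thickness, row$rotation_deg,
                 row$height, row$diameter, full_solid = full_solid)
}

cell_sizes <- function(design) {
  c(design$cell_size_x, design$cell_size_y, design$cell_size_z)
}
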