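#' Supported TPMS surface families
#'
#' The level-set approximations used for each family, with coordinates
#' phase-scaled as `X = 2*pi*x/Lx` (and likewise for Y, Z):
#'
#' * **gyroid**: `sin(X)cos(Y) + sin(Y)cos(Z) + sin(Z)cos(X)`
#' * **diamond** (Schwarz D):
#'   `sin(X)sin(Y)sin(Z) + sin(X)cos(Y)cos(Z) + cos(X)sin(Y)cos(Z) + cos(X)cos(Y)sin(Z)`
#' * **split_p**:
#'   `1.1 (sin(2X)sin(Z)cos(Y) + sin(2Y)sin(X)cos(Z) + sin(2Z)sin(Y)cos(X))
#'    - 0.2 (cos(2X)cos(2Y) + cos(2Y)cos(2Z) + cos(2Z)cos(2X))
#'    - 0.4 (cos(2X) + cos(2Y) + cos(2Z))`
#'
#' These are the standard published trigonometric forms; the Split-P
#' coefficients follow its common literature parameterization.
#'
#' @return Character vector of supported surface type names.
#' @export
tpms_surfaces <- function() c("gyroid", "diamond", "split_p")

surface_expression <- function(type, X, Y, Z) {
  switch(type,
    gyroid = sin(X) * cos(Y) + sin(Y) * cos(Z) + sin(Z) * cos(X),
    diamond = sin(X) * sin(Y) * sin(Z) + sin(X) * cos(Y) * cos(Z) +
      cos(X) * sin(Y) * cos(Z) + cos(X) * cos(Y) * sin(Z),
    split_p = 1.1 * (sin(2 * X) * sin(Z) * cos(Y) +
                     sin(2 * Y) * sin(X) * cos(Z) +
                     sin(2 * Z) * sin(Y) * cos(X)) -
      0.2 * (cos(2 * X) * cos(2 * Y) + cos(2 * Y) * cos(2 * Z) +
             cos(2 * Z) * cos(2 * X)) -
      0.4 * (cos(2 * X) + cos(2 * Y) + cos(2 * Z)),
    abort(paste0("unsupported surface type '", type, "'; use one of: ",
                 paste(tpms_surfaces(), collapse = ", ")),
          class = "tpmsdesign_unsupported_surface")
  )
}

# Rotation about the X axis by `deg` degrees, applied to an n x 3 matrix of
# points (coordinates are rotated before field evaluation).
rotate_about_x <- function(pts, deg) {
  if (deg == 0) return(pts)
  th <- deg * pi / 180
  cbind(pts[, 1],
        cos(th) * pts[, 2] - sin(th) * pts[, 3],
        sin(th) * pts[, 2] + cos(th) * pts[, 3])
}

#' Evaluate a TPMS implicit field
#'
#' Evaluates the level-set expression of the chosen surface family at one or
#' more points. Points are first rotated about the X axis by `rotation_deg`,
#' then each coordinate is phase-scaled by `2*pi / cell_size` before the
#' trigonometric expression is evaluated. The field is periodic with period
#' `cell_sizes` along each (unrotated) axis and vanishes on the mid-surface.
#'
#' @param surface_type One of [tpms_surfaces()].
#' @param points Numeric 3-vector or an `n x 3` matrix of points (mm).
#' @param cell_sizes Numeric 3-vector of unit-cell sizes (mm), recycled from
#'   a scalar.
#' @param rotation_deg Rotation about the X axis in degrees (default 0).
#' @return Numeric vector of field values, one per point.
#' @examples
#' tpms_field("gyroid", c(0, 0, 0), c(3, 3, 4))
#' @export
tpms_field <- function(surface_type, points, cell_sizes, rotation_deg = 0) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cell_sizes <- rep_len(cell_sizes, 3)
  stopifnot(all(cell_sizes > 0), all(is.finite(points)))
  p <- rotate_about_x(points, rotation_deg)
  k <- 2 * pi / cell_sizes
  surface_expression(surface_type, k[1] * p[, 1], k[2] * p[, 2], k[3] * p[, 3])
}
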