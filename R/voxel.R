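# Central-difference step used for gradient-normalized distance, as a
# fraction of the smallest cell size.
GRAD_STEP_FRAC <- 1e-3
# Gradient norms below this (relative to the field's phase scale) trigger
# the bounded field-band fallback instead of a division.
GRAD_NORM_TOL <- 1e-8

# Field value and central-difference gradient norm at an n x 3 point matrix.
field_and_gradnorm <- function(design, pts) {
  L <- cell_sizes(design)
  h <- GRAD_STEP_FRAC * min(L)
  phi <- tpms_field(design$surface_type, pts, L, design$rotation_deg)
  gx <- (tpms_field(design$surface_type, pts + matrix(c(h, 0, 0), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg) -
         tpms_field(design$surface_type, pts - matrix(c(h, 0, 0), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg)) / (2 * h)
  gy <- (tpms_field(design$surface_type, pts + matrix(c(0, h, 0), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg) -
         tpms_field(design$surface_type, pts - matrix(c(0, h, 0), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg)) / (2 * h)
  gz <- (tpms_field(design$surface_type, pts + matrix(c(0, 0, h), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg) -
         tpms_field(design$surface_type, pts - matrix(c(0, 0, h), nrow(pts), 3, byrow = TRUE), L, design$rotation_deg)) / (2 * h)
  list(phi = phi, gnorm = sqrt(gx^2 + gy^2 + gz^2))
}

# First-order metric distance to the mid-surface, |phi| / ||grad phi||.
# Where the gradient degenerates (critical points of the field) the
# distance falls back to |phi| / k_bar, with k_bar the mean phase scale
# 2*pi/L — the typical gradient magnitude of the trigonometric field —
# so the test stays bounded and never divides by zero.
surface_distance <- function(design, pts) {
  fg <- field_and_gradnorm(design, pts)
  kbar <- mean(2 * pi / cell_sizes(design))
  denom <- ifelse(fg$gnorm < GRAD_NORM_TOL, kbar, fg$gnorm)
  abs(fg$phi) / denom
}

#' Test whether points lie inside the shell solid
#'
#' A point belongs to the lattice solid when it lies inside the cylindrical
#' envelope (`x^2 + y^2 <= (D/2)^2`, `0 <= z <= H`, cylinder axis = Z) and
#' its first-order metric distance to the TPMS mid-surface,
#' `|phi(p)| / ||grad phi(p)||` (gradient by central differences), is at most
#' half the shell thickness.
#'
#' @param design A [lattice_design()].
#' @param points Numeric 3-vector or `n x 3` matrix of points (mm).
#' @return Logical vector, one value per point.
#' @export
in_shell <- function(design, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r2 <- points[, 1]^2 + points[, 2]^2
  env <- r2 <= (design$diameter / 2)^2 &
    points[, 3] >= 0 & points[, 3] <= design$height
  if (design$full_solid) return(env)
  out <- env
  if (any(env)) {
    d <- surface_distance(design, points[env, , drop = FALSE])
    out[env] <- d <= design$thickness / 2
  }
  out
}

#' Voxelize a lattice design
#'
#' Samples [in_shell()] at voxel centers on a regular grid that tightly
#' covers the cylindrical envelope.
#'
#' @param design A [lattice_design()].
#' @param spacing Voxel edge length (mm); must not exceed `thickness / 2`
#'   (a warning is issued above `thickness / 4`).
#' @param max_cells Memory budget as a maximum grid cell count; exceeding it
#'   raises a resolution error with a suggested spacing.
#' @return A `voxel_grid`: list with `origin`, `spacing`, `shape`,
#'   `occupancy` (logical array), `in_envelope` (logical array) and the
#'   design.
#' @export
voxelize <- function(design, spacing, max_cells = 2.5e7) {
  stopifnot(spacing > 0)
  if (!design$full_solid && spacing > design$thickness / 2) {
    abort(sprintf("spacing %.4g exceeds thickness/2 = %.4g; shell would be under-resolved",
                  spacing, design$thickness / 2),
          class = "tpmsdesign_resolution_error")
  }
  if (!design$full_solid && spacing > design$thickness / 4) {
    warn(sprintf("spacing %.4g above thickness/4 = %.4g; descriptors may be coarse",
                 spacing, design$thickness / 4))
  }
  D <- design$diameter; H <- design$height
  nx <- ceiling(D / spacing); ny <- nx; nz <- ceiling(H / spacing)
  ncell <- as.double(nx) * ny * nz
  if (ncell > max_cells) {
    sugg <- spacing * (ncell / max_cells)^(1 / 3)
    abort(sprintf("grid of %.3g cells exceeds budget %.3g; try spacing >= %.4g",
                  ncell, max_cells, sugg),
          class = "tpmsdesign_resolution_error")
  }
  origin <- c(-nx * spacing / 2, -ny * spacing / 2, 0)
  xs <- origin[1] + (seq_len(nx) - 0.5) * spacing
  ys <- origin[2] + (seq_len(ny) - 0.5) * spacing
  zs <- origin[3] + (seq_len(nz) - 0.5) * spacing

  occ <- array(FALSE, dim = c(nx, ny, nz))
  env <- array(FALSE, dim = c(nx, ny, nz))
  xy <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  in_disc <- xy[, 1]^2 + xy[, 2]^2 <= (D / 2)^2
  # z-slab chunks bound peak memory: 7 field evaluations per point.
  chunk <- max(1L, floor(2e6 / sum(in_disc)))
  for (z0 in seq(1L, nz, by = chunk)) {
    z1 <- min(nz, z0 + chunk - 1L)
    for (k in z0:z1) {
      env[, , k] <- in_disc
      if (zs[k] < 0 || zs[k] > H) env[, , k] <- FALSE
    }
    idx <- which(in_disc)
    pts <- cbind(xy[rep(idx, z1 - z0 + 1L), , drop = FALSE],
                 rep(zs[z0:z1], each = length(idx)))
    if (design$full_solid) {
      inside <- rep(TRUE, nrow(pts))
    } else {
      inside <- surface_distance(design, pts) <= design$thickness / 2
    }
    m <- matrix(FALSE, nrow = nx * ny, ncol = z1 - z0 + 1L)
    m[idx, ] <- matrix(inside, ncol = z1 - z0 + 1L)
    occ[, , z0:z1] <- array(m, dim = c(nx, ny, z1 - z0 + 1L))
  }
  structure(list(origin = origin, spacing = spacing, shape = c(nx, ny, nz),
                 occupancy = occ, in_envelope = env, design = design),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %.3g mm | %d occupied of %d in-envelope cells\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              sum(x$occupancy), sum(x$in_envelope)))
  invisible(x)
}
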