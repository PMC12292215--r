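#' Build an engineering stress-strain curve
#'
#' Converts force-displacement records from a uniaxial compression test of a
#' cylindrical lattice into engineering stress and strain. Stress is
#' normalized by the envelope cross-section `pi (D/2)^2` (the cellular-solids
#' convention: lattice stress, not solid-material stress); strain is
#' displacement over specimen height.
#'
#' @param force Force samples (N).
#' @param displacement Displacement samples (mm), non-decreasing.
#' @param diameter,height Specimen envelope dimensions (mm).
#' @return A tibble with `strain` and `stress` (MPa) columns, of class
#'   `stress_strain_curve`.
#' @export
engineering_curve <- function(force, displacement, diameter, height) {
  stopifnot(length(force) == length(displacement), diameter > 0, height > 0)
  bad <- which(diff(displacement) < 0)
  if (length(bad) > 0) {
    abort(sprintf("displacement is not non-decreasing (first violation at index %d)",
                  bad[1] + 1L),
          class = "tpmsdesign_curve_error")
  }
  new_curve(displacement / height, force / (pi * (diameter / 2)^2))
}

new_curve <- function(strain, stress) {
  stopifnot(length(strain) == length(stress), length(strain) >= 2)
  if (any(strain < 0) || any(diff(strain) <= 0)) {
    abort("strain must be non-negative and strictly increasing",
          class = "tpmsdesign_curve_error")
  }
  if (any(stress < 0)) {
    abort("stress must be non-negative", class = "tpmsdesign_curve_error")
  }
  structure(tibble(strain = strain, stress = stress),
            class = c("stress_strain_curve", class(tibble())))
}

#' Stress-strain curve from strain/stress samples
#'
#' @param strain Engineering strain samples, strictly increasing, >= 0.
#' @param stress Engineering stress samples (MPa), >= 0.
#' @return A `stress_strain_curve` tibble.
#' @export
stress_strain_curve <- function(strain, stress) new_curve(strain, stress)

#' Ultimate stress of a compression curve
#'
#' The maximum engineering stress reached during compression.
#'
#' @param curve A [stress_strain_curve()].
#' @return Ultimate stress (MPa).
#' @export
ultimate_stress <- function(curve) max(curve$stress)

#' Energy absorption up to a strain limit
#'
#' Trapezoidal integral of stress over strain on `[0, strain_limit]`, with
#' linear interpolation of the segment crossing the limit. MPa integrated
#' over dimensionless strain is volumetric energy, MJ/m^3. If the curve
#' ends before the limit the integral runs to the curve end and the result
#' carries a `truncated` attribute (with a warning).
#'
#' @param curve A [stress_strain_curve()].
#' @param strain_limit Upper strain bound (default 0.5).
#' @return Energy absorption (MJ/m^3), with attribute `truncated`.
#' @export
energy_absorption <- function(curve, strain_limit = 0.5) {
  stopifnot(strain_limit > 0)
  eps <- curve$strain; sig <- curve$stress
  truncated <- FALSE
  if (max(eps) < strain_limit) {
    warn(sprintf("curve ends at strain %.4g before limit %.4g; integrating to curve end",
                 max(eps), strain_limit))
    truncated <- TRUE
  } else if (max(eps) > strain_limit) {
    keep <- eps <= strain_limit
    s_lim <- stats::approx(eps, sig, xout = strain_limit)$y
    eps <- c(eps[keep], strain_limit)
    sig <- c(sig[keep], s_lim)
  }
  ea <- sum(diff(eps) * (head(sig, -1) + tail(sig, -1)) / 2)
  structure(ea, truncated = truncated)
}

#' Extended mechanical metrics of a compression curve
#'
#' Beyond ultimate stress and energy absorption:
#'
#' * **Young's modulus**: least-squares slope of stress vs strain over the
#'   samples whose stress lies in a window of the ultimate stress (default
#'   10-40%), a deterministic proxy for the initial quasi-linear region.
#' * **Yield strength**: 0.2%-offset intersection; if the offset line never
#'   crosses the curve, the first local maximum is reported and flagged.
#' * **Plateau stress**: mean stress over a strain window (default
#'   `[0.2, 0.4]`), the cellular-solids plateau convention.
#'
#' @param curve A [stress_strain_curve()].
#' @param modulus_window Stress window for the modulus fit, as fractions of
#'   ultimate stress.
#' @param plateau_window Strain window for the plateau mean.
#' @param offset Strain offset for the yield construction (default 0.002).
#' @return One-row tibble: `ultimate_stress`, `energy_absorption`,
#'   `youngs_modulus`, `yield_strength`, `plateau_stress`, `yield_flagged`.
#' @export
mech_metrics <- function(curve, modulus_window = c(0.1, 0.4),
                         plateau_window = c(0.2, 0.4), offset = 0.002) {
  u <- ultimate_stress(curve)
  ea <- as.numeric(suppressWarnings(energy_absorption(curve)))
  sel <- curve$stress >= modulus_window[1] * u &
    curve$stress <= modulus_window[2] * u & curve$strain > 0
  E <- if (sum(sel) >= 2) {
    unname(coef(lm(stress ~ strain, data = curve[sel, ]))[2])
  } else {
    # fewer than two window samples: secant through the first rising point
    i <- which(curve$stress > 0)[1]
    curve$stress[i] / curve$strain[i]
  }
  # 0.2%-offset yield: first crossing of stress - E*(strain - offset) = 0
  gap <- curve$stress - E * (curve$strain - offset)
  cross <- which(head(gap, -1) > 0 & tail(gap, -1) <= 0)
  if (length(cross) > 0) {
    i <- cross[1]
    w <- gap[i] / (gap[i] - gap[i + 1])
    yield <- curve$stress[i] + w * (curve$stress[i + 1] - curve$stress[i])
    flagged <- FALSE
  } else {
    peaks <- which(diff(sign(diff(curve$stress))) < 0) + 1L
    yield <- if (length(peaks) > 0) curve$stress[peaks[1]] else u
    flagged <- TRUE
  }
  pl_sel <- curve$strain >= plateau_window[1] & curve$strain <= plateau_window[2]
  plateau <- if (any(pl_sel)) mean(curve$stress[pl_sel]) else NA_real_
  tibble(ultimate_stress = u, energy_absorption = ea, youngs_modulus = E,
         yield_strength = yield, plateau_stress = plateau,
         yield_flagged = flagged)
}

#' Johnson-Cook failure strain
#'
#' Evaluates the empirical failure-strain law
#' `eps_f = (d1 + d2 exp(d3 eta)) (1 + d4 * rate_term) (1 + d5 * temp_term)`
#' where `eta` is the stress triaxiality. The default damage constants are
#' the calibration used for Ti6Al4V shell lattices under compression
#' (`d1 = 0.005`, `d2 = 0.55`, `d3 = -0.25`, `d4 = d5 = 0`).
#'
#' @param triaxiality Stress triaxiality `eta` (dimensionless), vectorized.
#' @param d1,d2,d3,d4,d5 Damage constants.
#' @param rate_term Logarithmic dimensionless strain-rate term.
#' @param temp_term Homologous temperature term.
#' @return Failure strain (dimensionless).
#' @examples
#' jc_failure_strain(0) # 0.555
#' @export
jc_failure_strain <- function(triaxiality, d1 = 0.005, d2 = 0.55, d3 = -0.25,
                              d4 = 0, d5 = 0, rate_term = 0, temp_term = 0) {
  stopifnot(all(is.finite(triaxiality)) || all(is.infinite(triaxiality) | is.finite(triaxiality)))
  (d1 + d2 * exp(d3 * triaxiality)) * (1 + d4 * rate_term) * (1 + d5 * temp_term)
}

#' Reference material constants
#'
#' Metadata carried for provenance: the Ti6Al4V elastic constants and the
#' density used by the mass-scaled explicit simulations this toolkit's
#' synthetic generator stands in for. These values are configuration
#' metadata only; no solver in this package consumes them.
#'
#' @return Named list of material constants.
#' @export
material_metadata <- function() {
  list(material = "Ti6Al4V", youngs_modulus_gpa = 107.5, poisson_ratio = 0.3,
       density_kg_m3 = 10750,
       jc_damage = c(d1 = 0.005, d2 = 0.55, d3 = -0.25, d4 = 0, d5 = 0))
}
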