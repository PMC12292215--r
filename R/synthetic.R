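#' Configuration of the synthetic mechanical-response generator
#'
#' The generator emulates an FEA-derived property table for shell TPMS
#' lattices so the modelling and optimization stages can be exercised
#' offline. Ultimate stress follows a Gibson-Ashby-style power law in
#' relative density,
#' `U = k_type * base_strength * (RD/100)^density_exponent`, modulated by
#' small documented rotation and slenderness factors and multiplicative
#' lognormal noise; energy absorption integrates an idealized
#' elastic-plateau curve with plateau stress `plateau_fraction * U` up to a
#' strain of 0.5.
#'
#' @param base_strength Solid-material strength scale (MPa); default 1000,
#'   the order of Ti6Al4V yield.
#' @param density_exponent Gibson-Ashby exponent; default 1.5
#'   (bending-dominated lattices).
#' @param type_multipliers Named strength multipliers per surface family.
#' @param plateau_fraction Plateau stress as a fraction of ultimate stress.
#' @param modulus_scale Effective modulus scale (MPa) for the elastic strain
#'   of the idealized curve, applied as `E = modulus_scale * (RD/100)^2`.
#' @param rotation_amplitude,slenderness_coeff Amplitudes of the rotation
#'   harmonic and height/diameter slenderness penalty.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 disables noise).
#' @param seed Integer seed; the generator is bit-reproducible given a seed.
#' @return A `response_config` list.
#' @export
response_config <- function(base_strength = 1000, density_exponent = 1.5,
                            type_multipliers = c(gyroid = 1.0, diamond = 1.1,
                                                 split_p = 0.85),
                            plateau_fraction = 0.85, modulus_scale = 1e5,
                            rotation_amplitude = 0.05,
                            slenderness_coeff = 0.04,
                            noise_cv = 0.02, seed = 1L) {
  stopifnot(base_strength > 0, density_exponent > 0,
            plateau_fraction > 0, plateau_fraction <= 1, noise_cv >= 0)
  structure(list(base_strength = base_strength,
                 density_exponent = density_exponent,
                 type_multipliers = type_multipliers,
                 plateau_fraction = plateau_fraction,
                 modulus_scale = modulus_scale,
                 rotation_amplitude = rotation_amplitude,
                 slenderness_coeff = slenderness_coeff,
                 noise_cv = noise_cv, seed = seed),
            class = "response_config")
}

#' Simulate mechanical responses for a design table
#'
#' Appends `ultimate_stress` (MPa) and `energy_absorption` (MJ/m^3) columns
#' to a design table that already carries `relative_density` (attach one
#' with [approx_descriptors()] or [compute_descriptors()]). Deterministic
#' given `config$seed`; independent lognormal noise draws (unit mean,
#' coefficient of variation `noise_cv`) are applied to U and EA.
#'
#' @param designs Design tibble with a `relative_density` column (%).
#' @param config A [response_config()].
#' @return `designs` with `ultimate_stress` and `energy_absorption`
#'   appended.
#' @export
simulate_responses <- function(designs, config = response_config()) {
  if (!"relative_density" %in% names(designs)) {
    abort("designs must carry a relative_density column; see approx_descriptors()",
          class = "tpmsdesign_missing_rd")
  }
  missing_rd <- which(!is.finite(designs$relative_density))
  if (length(missing_rd) > 0) {
    abort(paste0("missing relative_density for design row(s): ",
                 paste(head(missing_rd, 10), collapse = ", ")),
          class = "tpmsdesign_missing_rd")
  }
  rd <- designs$relative_density / 100
  k_type <- config$type_multipliers[designs$surface_type]
  rot <- designs$rotation_deg * pi / 180
  slender <- designs$height / designs$diameter
  u0 <- config$base_strength * unname(k_type) * rd^config$density_exponent *
    (1 + config$rotation_amplitude * sin(2 * rot)) *
    (1 - config$slenderness_coeff * (slender - 1))
  # idealized elastic-plateau curve: linear to the plateau onset strain
  # eps_y = sigma_pl / E, then flat at sigma_pl up to eps = 0.5
  sigma_pl <- config$plateau_fraction * u0
  E_eff <- config$modulus_scale * rd^2
  eps_y <- pmin(sigma_pl / E_eff, 0.5)
  ea0 <- sigma_pl * (0.5 - eps_y / 2)
  n <- nrow(designs)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- with_seed(config$seed, {
      matrix(stats::rlnorm(2 * n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
             ncol = 2)
    })
  } else {
    noise <- matrix(1, n, 2)
  }
  dplyr::mutate(designs,
                ultimate_stress = u0 * noise[, 1],
                energy_absorption = ea0 * noise[, 2])
}

#' Build the full synthetic study dataset
#'
#' Convenience pipeline for the study conditions: enumerate the
#' full-factorial space, apply the aspect-ratio filter, classify sizes,
#' attach analytic descriptors and simulate responses.
#'
#' @param config A [design_space_config()].
#' @param response A [response_config()].
#' @return Tibble with designs, `size_class`, `relative_density`,
#'   `porosity`, `sa_vr`, `ultimate_stress`, `energy_absorption`.
#' @export
synthetic_dataset <- function(config = design_space_config(),
                              response = response_config()) {
  enumerate_designs(config) %>%
    filter_aspect_ratio(config$max_aspect_ratio) %>%
    add_size_class() %>%
    approx_descriptors() %>%
    simulate_responses(response)
}
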