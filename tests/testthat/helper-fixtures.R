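# Shared fixtures. The study-scale dataset and surrogate are expensive to
# build, so they are computed once per test run and cached.

study_cache <- new.env(parent = emptyenv())

study_dataset <- function() {
  if (is.null(study_cache$ds)) study_cache$ds <- synthetic_dataset()
  study_cache$ds
}

# 80/20 split + fitted surrogate + held-out evaluation under the study
# conditions (n = 3024, noise_cv = 0.02).
study_fit <- function() {
  if (is.null(study_cache$fit)) {
    ds <- study_dataset()
    sp <- split_dataset(ds, 0.8, seed = 42)
    m <- fit_surrogate(sp$train, surrogate_config(), validation = sp$test)
    study_cache$fit <- list(split = sp, model = m,
                            eval = evaluate_surrogate(m, sp$test))
  }
  study_cache$fit
}

# small, quick-to-voxelize test design
tiny_design <- function(thickness = 0.4, rotation = 0, type = "gyroid") {
  lattice_design(type, 3, 3, 3, thickness = thickness,
                 rotation_deg = rotation, height = 3, diameter = 4)
}

# random design tibble in natural units (for property tests)
random_designs <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    surface_type = sample(tpms_surfaces(), n, replace = TRUE),
    cell_size_x = runif(n, 3, 4), cell_size_y = runif(n, 3, 4),
    cell_size_z = runif(n, 3, 4), thickness = runif(n, 0.2, 0.4),
    rotation_deg = runif(n, 0, 60), height = runif(n, 8, 20),
    diameter = runif(n, 5, 20)
  ))
}

# O(n^3) brute-force non-dominated sorting oracle (maximization)
brute_force_fronts <- function(obj) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && dominates(obj[j, ], obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# canonical ZDT1 wrapped for maximization
zdt1_max <- function(pop) {
  f1 <- pop[, 1]
  g <- 1 + 9 * rowMeans(pop[, -1, drop = FALSE])
  f2 <- g * (1 - sqrt(f1 / g))
  cbind(-f1, -f2)
}

zdt1_front_distance <- function(result) {
  f1 <- -result$objectives[, 1]
  f2 <- -result$objectives[, 2]
  mean(abs(f2 - (1 - sqrt(f1))))
}
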