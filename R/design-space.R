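# The seven continuous/ordinal design variables of a lattice design.
DESIGN_VARS <- c("cell_size_x", "cell_size_y", "cell_size_z", "thickness",
                 "rotation_deg", "height", "diameter")

#' Design-space configuration
#'
#' Factor levels for the full-factorial sweep over the seven design
#' parameters, plus the aspect-ratio stability threshold. The defaults are
#' the study conditions: three surface families, cell sizes of 3 and 4 mm
#' per axis, shell thicknesses 0.2/0.3/0.4 mm, rotations 0/30/60 degrees,
#' heights 8/10/15/20 mm, diameters 5/10/15/20 mm, and a height-to-diameter
#' cap of 2 (squat columns resist buckling under compression).
#'
#' @param type_levels Surface families to sweep.
#' @param cell_levels_x,cell_levels_y,cell_levels_z Cell-size levels (mm).
#' @param thickness_levels Shell-thickness levels (mm).
#' @param rotation_levels Rotation-angle levels (degrees).
#' @param height_levels,diameter_levels Envelope dimension levels (mm).
#' @param max_aspect_ratio Maximum allowed height/diameter ratio.
#' @return A `design_space_config` list.
#' @export
design_space_config <- function(type_levels = tpms_surfaces(),
                                cell_levels_x = c(3, 4),
                                cell_levels_y = c(3, 4),
                                cell_levels_z = c(3, 4),
                                thickness_levels = c(0.2, 0.3, 0.4),
                                rotation_levels = c(0, 30, 60),
                                height_levels = c(8, 10, 15, 20),
                                diameter_levels = c(5, 10, 15, 20),
                                max_aspect_ratio = 2) {
  lvls <- list(type_levels = type_levels, cell_levels_x = cell_levels_x,
               cell_levels_y = cell_levels_y, cell_levels_z = cell_levels_z,
               thickness_levels = thickness_levels,
               rotation_levels = rotation_levels,
               height_levels = height_levels,
               diameter_levels = diameter_levels)
  if (any(lengths(lvls) == 0)) {
    abort("all level lists must be non-empty", class = "tpmsdesign_config_error")
  }
  if (!is.numeric(max_aspect_ratio) || max_aspect_ratio <= 0) {
    abort("max_aspect_ratio must be > 0", class = "tpmsdesign_config_error")
  }
  structure(c(lvls, list(max_aspect_ratio = max_aspect_ratio)),
            class = "design_space_config")
}

#' Enumerate the full-factorial design space
#'
#' Cartesian product of all level lists in deterministic lexicographic
#' order (last factor varying fastest).
#'
#' @param config A [design_space_config()].
#' @return A tibble with one row per design and columns `surface_type`,
#'   `cell_size_x/y/z`, `thickness`, `rotation_deg`, `height`, `diameter`.
#' @examples
#' nrow(enumerate_designs(design_space_config())) # 3456
#' @export
enumerate_designs <- function(config = design_space_config()) {
  tidyr::expand_grid(
    surface_type = config$type_levels,
    cell_size_x = config$cell_levels_x,
    cell_size_y = config$cell_levels_y,
    cell_size_z = config$cell_levels_z,
    thickness = config$thickness_levels,
    rotation_deg = config$rotation_levels,
    height = config$height_levels,
    diameter = config$diameter_levels
  )
}

#' Filter designs by aspect-ratio stability
#'
#' Retains designs whose height-to-diameter ratio does not exceed
#' `max_ratio`; slender columns are prone to buckling under compression.
#' Row order is preserved.
#'
#' @param designs Design tibble (needs `height` and `diameter`).
#' @param max_ratio Maximum height/diameter (default 2).
#' @return The retained subset of `designs`.
#' @export
filter_aspect_ratio <- function(designs, max_ratio = 2) {
  stopifnot(max_ratio > 0)
  dplyr::filter(designs, .data$height / .data$diameter <= max_ratio)
}

#' Classify designs by implant size
#'
#' Geometric size classes for anatomical stratification:
#' small when `H <= 8` and `D <= 8` mm; large when `H > 15` or `D > 15` mm;
#' medium otherwise (precedence: small, then large). The classes are
#' exhaustive and mutually exclusive.
#'
#' @param height,diameter Numeric vectors (mm).
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
classify_size <- function(height, diameter) {
  cls <- ifelse(height <= 8 & diameter <= 8, "small",
                ifelse(height > 15 | diameter > 15, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Append a `size_class` column to a design tibble
#'
#' @param designs Design tibble with `height` and `diameter`.
#' @return `designs` with a `size_class` factor column.
#' @export
add_size_class <- function(designs) {
  dplyr::mutate(designs,
                size_class = classify_size(.data$height, .data$diameter))
}

#' Fit a feature encoder/scaler on a design table
#'
#' Numeric features (`cell_size_x/y/z`, `thickness`, `rotation_deg`,
#' `height`, `diameter`) are z-scored with the fitted mean and standard
#' deviation; the surface type is one-hot encoded into
#' `type_gyroid`/`type_diamond`/`type_split_p` columns appended after the
#' scaled numerics. The fitted scaler is reusable on new designs and
#' invertible.
#'
#' @param designs Non-empty design tibble.
#' @return A `feature_scaler` storing per-feature means/sds and the type
#'   levels.
#' @export
fit_feature_scaler <- function(designs) {
  stopifnot(nrow(designs) > 0)
  num_cols <- c("cell_size_x", "cell_size_y", "cell_size_z", "thickness",
                "rotation_deg", "height", "diameter")
  mu <- vapply(designs[num_cols], mean, numeric(1))
  sig <- vapply(designs[num_cols], stats::sd, numeric(1))
  if (any(!is.finite(sig)) || any(sig == 0)) {
    bad <- num_cols[!is.finite(sig) | sig == 0]
    abort(paste0("zero-variance feature column(s): ", paste(bad, collapse = ", ")),
          class = "tpmsdesign_scaling_error")
  }
  structure(list(numeric_cols = num_cols, mean = mu, sd = sig,
                 type_levels = tpms_surfaces()),
            class = "feature_scaler")
}

#' Encode designs into the model feature matrix
#'
#' @param designs Design tibble.
#' @param scaler A fitted [fit_feature_scaler()]; fitted on `designs` when
#'   omitted.
#' @return List with `features` (numeric matrix, 7 scaled numerics + 3
#'   one-hot columns) and the `scaler`.
#' @export
encode_features <- function(designs, scaler = NULL) {
  if (is.null(scaler)) scaler <- fit_feature_scaler(designs)
  num <- as.matrix(designs[scaler$numeric_cols])
  num <- sweep(sweep(num, 2, scaler$mean), 2, scaler$sd, "/")
  onehot <- vapply(scaler$type_levels,
                   function(tl) as.numeric(designs$surface_type == tl),
                   numeric(nrow(designs)))
  if (nrow(designs) == 1) onehot <- matrix(onehot, nrow = 1)
  colnames(onehot) <- paste0("type_", scaler$type_levels)
  feats <- cbind(num, onehot)
  if (any(rowSums(onehot) != 1)) {
    abort("unknown surface type in designs", class = "tpmsdesign_scaling_error")
  }
  list(features = feats, scaler = scaler)
}

#' Invert feature encoding back to natural units
#'
#' @param features Matrix produced by [encode_features()].
#' @param scaler The matching `feature_scaler`.
#' @return Design tibble in natural units with a `surface_type` column.
#' @export
decode_features <- function(features, scaler) {
  num <- features[, scaler$numeric_cols, drop = FALSE]
  num <- sweep(sweep(num, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  onehot <- features[, paste0("type_", scaler$type_levels), drop = FALSE]
  type <- scaler$type_levels[max.col(onehot)]
  dplyr::bind_cols(as_tibble(num), tibble(surface_type = type))
}

#' Per-size-class summary of a property
#'
#' Five-number summary with outlier counts by the 1.5 IQR rule, per size
#' class, for boxplot-style comparisons. Empty classes are flagged with NA
#' rows rather than dropped.
#'
#' @param dataset Tibble with a `size_class` column.
#' @param property Name of the numeric column to summarise.
#' @return Tibble with one row per size class: `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `iqr`, `n_outliers`.
#' @export
group_summary <- function(dataset, property) {
  stopifnot(property %in% names(dataset))
  dataset %>%
    dplyr::group_by(.data$size_class, .drop = FALSE) %>%
    dplyr::summarise(
      n = dplyr::n(),
      min = suppressWarnings(min(.data[[property]])),
      q1 = stats::quantile(.data[[property]], 0.25, names = FALSE, type = 7),
      median = stats::median(.data[[property]]),
      q3 = stats::quantile(.data[[property]], 0.75, names = FALSE, type = 7),
      max = suppressWarnings(max(.data[[property]])),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      dplyr::across(c("min", "q1", "median", "q3", "max", "iqr"),
                    ~ ifelse(.data$n == 0, NA_real_, .x))
    ) %>%
    dplyr::left_join(
      dataset %>%
        dplyr::group_by(.data$size_class, .drop = FALSE) %>%
        dplyr::summarise(
          n_outliers = {
            x <- .data[[property]]
            if (length(x) == 0) NA_integer_ else {
              q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
              iqr <- q[2] - q[1]
              sum(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
            }
          },
          .groups = "drop"
        ),
      by = "size_class"
    )
}

#' Gaussian kernel density for group plotting
#'
#' Scott's-rule bandwidth Gaussian KDE of a property within each size
#' class, for KDE-style group comparisons.
#'
#' @inheritParams group_summary
#' @param n Grid resolution.
#' @return Tibble with `size_class`, `x`, `density`.
#' @export
group_density <- function(dataset, property, n = 256) {
  dataset %>%
    dplyr::group_by(.data$size_class) %>%
    dplyr::group_modify(function(df, key) {
      x <- df[[property]]
      if (length(x) < 2 || stats::sd(x) == 0) {
        return(tibble(x = unique(x), density = NA_real_))
      }
      bw <- stats::sd(x) * length(x)^(-1 / 5) # Scott's rule, 1-D
      d <- stats::density(x, bw = bw, n = n)
      tibble(x = d$x, density = d$y)
    }) %>%
    dplyr::ungroup()
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
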