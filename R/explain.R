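EXPLAIN_FEATURES <- c(DESIGN_VARS, "surface_type")

# Normalize a predictor: either a fitted tpms_surrogate (optionally with a
# named target) or any function(tibble) -> numeric vector.
as_predictor <- function(model, target = NULL) {
  if (inherits(model, "tpms_surrogate")) {
    target <- target %||% model$targets[1]
    function(df) predict(model, df)[[target]]
  } else {
    stopifnot(is.function(model))
    model
  }
}

#' One-factor-at-a-time sensitivity curve
#'
#' Varies one feature over an evenly spaced grid spanning its observed
#' range in `dataset`, holding every other numeric feature at its dataset
#' mean and the surface type at its modal level, and records the predicted
#' response. A categorical feature is enumerated over its levels instead of
#' gridded.
#'
#' @param model A fitted `tpms_surrogate` or a prediction function
#'   `function(tibble) -> numeric`.
#' @param dataset Design tibble defining ranges and means.
#' @param feature Feature name (a design variable or `"surface_type"`).
#' @param n_grid Grid resolution for numeric features.
#' @param target Target name when `model` is a surrogate.
#' @return Tibble with `feature`, `value` (natural units) and `response`.
#' @export
ofat_sensitivity <- function(model, dataset, feature, n_grid = 50,
                             target = NULL) {
  stopifnot(feature %in% EXPLAIN_FEATURES)
  fn <- as_predictor(model, target)
  base <- baseline_row(dataset)
  if (feature == "surface_type") {
    grid_vals <- sort(unique(dataset$surface_type))
  } else {
    rng <- range(dataset[[feature]])
    grid_vals <- seq(rng[1], rng[2], length.out = n_grid)
  }
  rows <- base[rep(1, length(grid_vals)), ]
  rows[[feature]] <- grid_vals
  tibble(feature = feature, value = grid_vals, response = fn(rows))
}

baseline_row <- function(dataset) {
  num <- lapply(dataset[intersect(DESIGN_VARS, names(dataset))], mean)
  modal <- names(sort(table(dataset$surface_type), decreasing = TRUE))[1]
  as_tibble(c(num, list(surface_type = modal)))
}

# Shapley kernel weights |S|!(p-1-|S|)!/p! indexed by coalition size 0..p-1.
shapley_weights <- function(p) {
  s <- 0:(p - 1)
  exp(lfactorial(s) + lfactorial(p - 1 - s) - lfactorial(p))
}

# Coalition value v(S): interventional expectation of the prediction with
# features in S pinned to the instance and the rest drawn from the
# background sample.
coalition_values <- function(fn, instance, background, features, masks) {
  nb <- nrow(background)
  big <- purrr::map_dfr(seq_len(nrow(masks)), function(m) {
    rows <- background
    on <- features[masks[m, ]]
    for (col in on) rows[[col]] <- instance[[col]]
    rows
  })
  preds <- fn(big)
  vapply(seq_len(nrow(masks)),
         function(m) mean(preds[((m - 1) * nb + 1):(m * nb)]),
         numeric(1))
}

#' Exact Shapley attribution by coalition enumeration
#'
#' Computes exact Shapley values for one design by enumerating all `2^p`
#' feature coalitions; absent features are marginalized interventionally by
#' averaging predictions over background replacements. The efficiency
#' property (base value plus attributions equals the prediction at the
#' instance averaged over the full coalition) holds by construction.
#'
#' @param model A fitted `tpms_surrogate` or prediction function.
#' @param instance One-row design tibble.
#' @param background Background design tibble (the interventional sample).
#' @param features Feature columns to attribute over (at most 13).
#' @param target Target name when `model` is a surrogate.
#' @return An `attribution` tibble (`feature`, `phi`) with attributes
#'   `base_value` and `prediction`.
#' @export
exact_shapley <- function(model, instance, background,
                          features = intersect(EXPLAIN_FEATURES, names(instance)),
                          target = NULL) {
  p <- length(features)
  if (p > 13) {
    abort("more than 13 features: coalition enumeration is 2^p; use sampled_shapley()",
          class = "tpmsdesign_shapley_cap")
  }
  stopifnot(nrow(instance) == 1, nrow(background) >= 1)
  fn <- as_predictor(model, target)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(masks) <- features
  v <- coalition_values(fn, instance, background, features, masks)
  sizes <- rowSums(masks)
  w <- shapley_weights(p)
  phi <- vapply(seq_len(p), function(i) {
    without <- which(!masks[, i])
    # index of S u {i}: flipping bit i adds 2^(i-1) in expand.grid order
    with_i <- without + 2^(i - 1)
    sum(w[sizes[without] + 1] * (v[with_i] - v[without]))
  }, numeric(1))
  structure(tibble(feature = features, phi = phi),
            base_value = v[1], prediction = v[length(v)],
            class = c("attribution", class(tibble())))
}

#' Permutation-sampling Shapley attribution
#'
#' Unbiased Monte-Carlo estimator: for each sampled feature permutation the
#' marginal contribution of every feature to its prefix coalition is
#' accumulated; values are interventional expectations over the background.
#' Reports per-feature Monte-Carlo standard errors and is reproducible per
#' seed.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer seed.
#' @return An `attribution` tibble (`feature`, `phi`, `se`) with attributes
#'   `base_value` and `prediction`.
#' @export
sampled_shapley <- function(model, instance, background,
                            n_permutations = 50, seed = 1L,
                            features = intersect(EXPLAIN_FEATURES, names(instance)),
                            target = NULL) {
  stopifnot(n_permutations >= 1, nrow(instance) == 1)
  fn <- as_predictor(model, target)
  p <- length(features)
  nb <- nrow(background)
  v_empty <- mean(fn(background))
  contrib <- with_seed(seed, {
    out <- matrix(NA_real_, n_permutations, p, dimnames = list(NULL, features))
    for (r in seq_len(n_permutations)) {
      perm <- sample(features)
      rows <- background[rep(seq_len(nb), p), ]
      for (step in seq_len(p)) {
        block <- ((step - 1) * nb + 1):(step * nb)
        for (col in perm[seq_len(step)]) {
          rows[block, col] <- instance[[col]]
        }
      }
      preds <- fn(rows)
      v_prev <- v_empty
      for (step in seq_len(p)) {
        v_cur <- mean(preds[((step - 1) * nb + 1):(step * nb)])
        out[r, perm[step]] <- v_cur - v_prev
        v_prev <- v_cur
      }
    }
    out
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  structure(tibble(feature = features, phi = unname(phi), se = unname(se)),
            base_value = v_empty, prediction = v_empty + sum(phi),
            class = c("attribution", class(tibble())))
}

#' Attribution distribution over a sample group
#'
#' Computes Shapley attributions for every (sub)sampled design in a group
#' and ranks features by mean absolute attribution — the data behind a
#' beeswarm-style summary plot.
#'
#' @param model A fitted `tpms_surrogate` or prediction function.
#' @param dataset Design tibble; rows with `size_class == group` are used
#'   when `group` is given.
#' @param target Target name when `model` is a surrogate.
#' @param group Optional size class to restrict to.
#' @param method `"exact"` or `"sampled"`.
#' @param n_background Background sample size (fixed-seed draw from the
#'   dataset).
#' @param n_samples Cap on the number of designs attributed.
#' @param n_permutations Permutations per design for the sampled method.
#' @param seed Integer seed for subsampling and the sampled estimator.
#' @return List: `attributions` (long tibble: `row`, `feature`,
#'   `feature_value`, `phi`) and `ranking` (tibble of `feature`,
#'   `mean_abs_phi`, ordered).
#' @export
summary_attributions <- function(model, dataset, target = NULL, group = NULL,
                                 method = c("exact", "sampled"),
                                 n_background = 100, n_samples = 30,
                                 n_permutations = 30, seed = 1L) {
  method <- match.arg(method)
  rows <- if (!is.null(group)) {
    dataset[dataset$size_class == group, , drop = FALSE]
  } else {
    dataset
  }
  if (nrow(rows) == 0) {
    abort("empty group", class = "tpmsdesign_config_error")
  }
  features <- intersect(EXPLAIN_FEATURES, names(rows))
  picks <- with_seed(seed, {
    bg <- dataset[sample.int(nrow(dataset), min(n_background, nrow(dataset))), ]
    smp <- rows[sample.int(nrow(rows), min(n_samples, nrow(rows))), ]
    list(bg = bg, smp = smp)
  })
  attributions <- purrr::map_dfr(seq_len(nrow(picks$smp)), function(i) {
    inst <- picks$smp[i, ]
    att <- if (method == "exact") {
      exact_shapley(model, inst, picks$bg, features, target)
    } else {
      sampled_shapley(model, inst, picks$bg, n_permutations,
                      seed = seed + i, features = features, target = target)
    }
    fvals <- vapply(features, function(f) {
      v <- inst[[f]]
      if (is.numeric(v)) v else NA_real_
    }, numeric(1))
    tibble(row = i, feature = att$feature, feature_value = unname(fvals),
           phi = att$phi)
  })
  ranking <- attributions %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(mean_abs_phi = mean(abs(.data$phi)), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$mean_abs_phi))
  list(attributions = attributions, ranking = ranking)
}
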