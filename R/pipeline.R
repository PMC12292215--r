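#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations plus the seeds that make the whole
#' run reproducible: design-space sweep, synthetic responses, surrogate
#' training, per-group NSGA-II, relative-density filtering, and attribution.
#'
#' @param space A [design_space_config()].
#' @param response A [response_config()].
#' @param surrogate A [surrogate_config()].
#' @param nsga An [nsga_config()].
#' @param rd_band Length-2 inclusive relative-density band (%).
#' @param attribution_target Target attributed in the final stage.
#' @param n_attribution_samples,n_background Attribution problem sizes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(space = design_space_config(),
                            response = response_config(),
                            surrogate = surrogate_config(),
                            nsga = nsga_config(),
                            rd_band = c(20, 40),
                            attribution_target = "ultimate_stress",
                            n_attribution_samples = 25,
                            n_background = 60) {
  structure(list(space = space, response = response, surrogate = surrogate,
                 nsga = nsga, rd_band = rd_band,
                 attribution_target = attribution_target,
                 n_attribution_samples = n_attribution_samples,
                 n_background = n_background),
            class = "pipeline_config")
}

#' Run the full design-optimization pipeline
#'
#' Sweep, filter and classify the design space; attach analytic descriptors
#' and simulated responses; split and train the surrogate; run NSGA-II per
#' implant-size group; filter each front by relative density; and rank
#' feature attributions for the chosen target.
#'
#' @param config A [pipeline_config()].
#' @return A `tpms_pipeline` list: `dataset`, `split`, `model`,
#'   `evaluation`, `fronts` (per group), `filtered` (per group, post
#'   RD-filter), and `attribution` (summary ranking).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dataset <- synthetic_dataset(config$space, config$response)
  split <- split_dataset(dataset, config$surrogate$train_fraction,
                         seed = config$surrogate$seed)
  model <- fit_surrogate(split$train, config$surrogate,
                         validation = split$test)
  evaluation <- evaluate_surrogate(model, split$test)
  groups <- levels(dataset$size_class)
  fronts <- lapply(setNames(groups, groups), function(g) {
    optimize_group(model, dataset, g, config$nsga)
  })
  filtered <- lapply(fronts, rd_filter,
                     low = config$rd_band[1], high = config$rd_band[2])
  attribution <- summary_attributions(
    model, dataset, target = config$attribution_target,
    method = "exact", n_background = config$n_background,
    n_samples = config$n_attribution_samples,
    seed = config$surrogate$seed)
  structure(list(dataset = dataset, split = split, model = model,
                 evaluation = evaluation, fronts = fronts,
                 filtered = filtered, attribution = attribution,
                 config = config),
            class = "tpms_pipeline")
}

#' @export
print.tpms_pipeline <- function(x, ...) {
  cat("<tpms_pipeline>\n")
  cat(sprintf("  dataset: %d designs (%s)\n", nrow(x$dataset),
              paste(sprintf("%s %d", levels(x$dataset$size_class),
                            table(x$dataset$size_class)), collapse = ", ")))
  r2 <- x$evaluation$metrics
  cat(sprintf("  surrogate R^2: %s\n",
              paste(sprintf("%s %.3f", r2$target, r2$r_squared), collapse = ", ")))
  for (g in names(x$fronts)) {
    cat(sprintf("  %s front: %d designs, %d after RD filter\n",
                g, nrow(x$fronts[[g]]), x$filtered[[g]]$n_retained))
  }
  cat(sprintf("  top feature for %s: %s\n", x$config$attribution_target,
              x$attribution$ranking$feature[1]))
  invisible(x)
}

#' Combined front table of a pipeline run
#'
#' @param x A `tpms_pipeline`.
#' @param filtered Return only RD-retained designs?
#' @param ... Unused.
#' @return Tibble of all groups' Pareto designs.
#' @export
tidy.tpms_pipeline <- function(x, filtered = FALSE, ...) {
  src <- if (filtered) lapply(x$filtered, `[[`, "retained") else x$fronts
  purrr::map_dfr(src, as_tibble)
}

#' One-row summary of a pipeline run
#'
#' @param x A `tpms_pipeline`.
#' @param ... Unused.
#' @return One-row tibble of dataset and front bookkeeping.
#' @export
glance.tpms_pipeline <- function(x, ...) {
  tibble(n_designs = nrow(x$dataset),
         n_train = nrow(x$split$train), n_test = nrow(x$split$test),
         min_test_r_squared = min(x$evaluation$metrics$r_squared),
         n_pareto = sum(vapply(x$fronts, nrow, integer(1))),
         n_retained = sum(vapply(x$filtered, `[[`, integer(1), "n_retained")),
         top_feature = x$attribution$ranking$feature[1])
}
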