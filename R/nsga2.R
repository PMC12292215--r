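#' NSGA-II configuration
#'
#' Defaults: population 100, 50 generations, SBX distribution index 15 at
#' crossover probability 0.9, polynomial-mutation index 20 at a
#' per-variable probability of `1/n_variables` (set when the variable count
#' is known).
#'
#' @param population_size Even population size.
#' @param generations Number of generations.
#' @param crossover_eta,crossover_prob SBX distribution index and pair
#'   crossover probability.
#' @param mutation_eta,mutation_prob Polynomial-mutation index and
#'   per-variable probability (`NULL` = `1/n_variables`).
#' @param seed Integer seed; runs are deterministic per seed.
#' @return An `nsga_config` list.
#' @export
nsga_config <- function(population_size = 100, generations = 50,
                        crossover_eta = 15, crossover_prob = 0.9,
                        mutation_eta = 20, mutation_prob = NULL,
                        seed = 7L) {
  stopifnot(population_size >= 4, population_size %% 2 == 0,
            generations >= 1, crossover_prob > 0, crossover_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_eta = crossover_eta, crossover_prob = crossover_prob,
                 mutation_eta = mutation_eta, mutation_prob = mutation_prob,
                 seed = as.integer(seed)),
            class = "nsga_config")
}

#' Pareto dominance (maximization)
#'
#' `a` dominates `b` when `a >= b` in every objective with at least one
#' strict inequality.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(a >= b) && any(a > b)
}

# N x N dominance matrix: dom[i, j] iff row i dominates row j.
dominance_matrix <- function(obj) {
  n <- nrow(obj)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    ge <- ge & outer(obj[, k], obj[, k], ">=")
    gt <- gt | outer(obj[, k], obj[, k], ">")
  }
  ge & gt
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts F0, F1, ... in the
#' maximization sense: every member of front k is non-dominated within the
#' union of fronts k and beyond.
#'
#' @param objectives Numeric matrix, one row per individual.
#' @return List of integer index vectors, one per front.
#' @export
fast_non_dominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 1) return(list(1L))
  dom <- dominance_matrix(objectives)
  n_dominators <- colSums(dom)
  fronts <- list()
  assigned <- rep(FALSE, n)
  while (!all(assigned)) {
    current <- which(!assigned & n_dominators == 0)
    fronts[[length(fronts) + 1]] <- current
    assigned[current] <- TRUE
    # removing the current front releases its dominance counts
    if (length(current) == 1) {
      n_dominators <- n_dominators - dom[current, ]
    } else {
      n_dominators <- n_dominators - colSums(dom[current, , drop = FALSE])
    }
  }
  fronts
}

#' Crowding distance within a front
#'
#' Per objective, boundary individuals receive infinite distance; interior
#' individuals accumulate the range-normalized gap between their sorted
#' neighbours. An objective with zero range contributes nothing.
#'
#' @param objectives Numeric matrix of the front's objective vectors.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (k in seq_len(ncol(objectives))) {
    ord <- order(objectives[, k])
    rng <- objectives[ord[n], k] - objectives[ord[1], k]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      gaps <- (objectives[ord[3:n], k] - objectives[ord[1:(n - 2)], k]) / rng
      dist[ord[2:(n - 1)]] <- dist[ord[2:(n - 1)]] + gaps
    }
  }
  dist
}

#' Simulated binary crossover
#'
#' Deb's bounded SBX as in the canonical NSGA-II implementation: with
#' probability `crossover_prob` a parent pair is crossed; each variable
#' then mixes with probability 0.5 using a spread factor drawn from the
#' polynomial distribution with index `crossover_eta`, with the
#' distribution truncated against the variable bounds so children lie
#' inside them by construction. The two child values of a crossed variable
#' are swapped with probability 0.5. Identical parents yield identical
#' children; as the index grows, the child pair concentrates at the parent
#' values.
#'
#' @param p1,p2 Parent decision vectors.
#' @param lower,upper Bounds vectors.
#' @param config An [nsga_config()].
#' @return List of two child vectors.
#' @export
sbx_crossover <- function(p1, p2, lower, upper, config = nsga_config()) {
  c1 <- p1; c2 <- p2
  if (runif(1) <= config$crossover_prob) {
    cross <- runif(length(p1)) <= 0.5 & abs(p1 - p2) > 1e-14
    if (any(cross)) {
      eta <- config$crossover_eta
      y1 <- pmin(p1[cross], p2[cross]); y2 <- pmax(p1[cross], p2[cross])
      lo <- lower[cross]; hi <- upper[cross]
      u <- runif(sum(cross))
      betaq <- function(u, beta) {
        alpha <- 2 - beta^-(eta + 1)
        ifelse(u <= 1 / alpha, (u * alpha)^(1 / (eta + 1)),
               (1 / (2 - u * alpha))^(1 / (eta + 1)))
      }
      b1 <- betaq(u, 1 + 2 * (y1 - lo) / (y2 - y1))
      b2 <- betaq(u, 1 + 2 * (hi - y2) / (y2 - y1))
      ch1 <- pmin(pmax(0.5 * ((y1 + y2) - b1 * (y2 - y1)), lo), hi)
      ch2 <- pmin(pmax(0.5 * ((y1 + y2) + b2 * (y2 - y1)), lo), hi)
      swap <- runif(sum(cross)) <= 0.5
      c1[cross] <- ifelse(swap, ch2, ch1)
      c2[cross] <- ifelse(swap, ch1, ch2)
    }
  }
  list(c1, c2)
}

#' Polynomial mutation
#'
#' Deb's bounded polynomial mutation with index `mutation_eta`, applied
#' per variable with probability `mutation_prob`; results stay within
#' bounds. A mutation probability of zero is the identity.
#'
#' @param x Decision vector.
#' @inheritParams sbx_crossover
#' @return Mutated decision vector.
#' @export
polynomial_mutation <- function(x, lower, upper, config = nsga_config()) {
  pm <- config$mutation_prob %||% (1 / length(x))
  mut <- runif(length(x)) < pm
  if (!any(mut)) return(x)
  eta <- config$mutation_eta
  lo <- lower[mut]; hi <- upper[mut]; xi <- x[mut]
  rng <- hi - lo
  u <- runif(sum(mut))
  d1 <- (xi - lo) / rng
  d2 <- (hi - xi) / rng
  dq <- ifelse(u < 0.5,
               (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1,
               1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1)))
  x[mut] <- pmin(pmax(xi + dq * rng, lo), hi)
  x
}

# Binary tournament on (rank, crowding): lower rank wins, ties broken by
# larger crowding distance, then by the first contender.
tournament_pick <- function(rank, crowd) {
  cand <- sample.int(length(rank), 2)
  i <- cand[1]; j <- cand[2]
  if (rank[j] < rank[i] || (rank[j] == rank[i] && crowd[j] > crowd[i])) j else i
}

rank_and_crowd <- function(obj) {
  fronts <- fast_non_dominated_sort(obj)
  rank <- integer(nrow(obj))
  crowd <- numeric(nrow(obj))
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    rank[idx] <- f - 1L
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd, fronts = fronts)
}

#' Run the NSGA-II loop
#'
#' Standard elitist NSGA-II in the maximization sense: random initial
#' population within bounds, binary tournaments on (rank, crowding), SBX
#' and polynomial mutation, and environmental selection over the combined
#' parent/offspring population with crowding-distance truncation of the
#' last admitted front. Deterministic per `config$seed`.
#'
#' @param evaluate Function mapping an `n x n_var` decision matrix to an
#'   `n x n_obj` objective matrix (all objectives maximized).
#' @param lower,upper Decision-variable bounds.
#' @param config An [nsga_config()].
#' @return List: `decisions` and `objectives` of the final rank-0 front,
#'   `history` (per-generation best of each objective), and the config.
#' @export
run_nsga2 <- function(evaluate, lower, upper, config = nsga_config()) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  nv <- length(lower)
  np <- config$population_size
  with_seed(config$seed, {
    pop <- matrix(runif(np * nv, rep(lower, each = np), rep(upper, each = np)),
                  np, nv)
    obj <- eval_population(evaluate, pop, 0L)
    history <- matrix(NA_real_, config$generations, ncol(obj))
    for (gen in seq_len(config$generations)) {
      rc <- rank_and_crowd(obj)
      children <- matrix(NA_real_, np, nv)
      for (i in seq(1L, np, by = 2L)) {
        pa <- pop[tournament_pick(rc$rank, rc$crowd), ]
        pb <- pop[tournament_pick(rc$rank, rc$crowd), ]
        off <- sbx_crossover(pa, pb, lower, upper, config)
        children[i, ] <- polynomial_mutation(off[[1]], lower, upper, config)
        children[i + 1L, ] <- polynomial_mutation(off[[2]], lower, upper, config)
      }
      cobj <- eval_population(evaluate, children, gen)
      all_pop <- rbind(pop, children)
      all_obj <- rbind(obj, cobj)
      sel <- environmental_selection(all_obj, np)
      pop <- all_pop[sel, , drop = FALSE]
      obj <- all_obj[sel, , drop = FALSE]
      history[gen, ] <- apply(obj, 2, max)
    }
    final <- fast_non_dominated_sort(obj)[[1]]
    list(decisions = pop[final, , drop = FALSE],
         objectives = obj[final, , drop = FALSE],
         history = as_tibble(setNames(as.data.frame(history),
                                      paste0("best_obj", seq_len(ncol(obj))))) %>%
           dplyr::mutate(generation = dplyr::row_number(), .before = 1),
         config = config)
  })
}

eval_population <- function(evaluate, pop, gen) {
  obj <- tryCatch(evaluate(pop), error = function(e) {
    abort(sprintf("evaluator failed at generation %d (%d individuals): %s",
                  gen, nrow(pop), conditionMessage(e)),
          class = "tpmsdesign_evaluator_error")
  })
  obj <- as.matrix(obj)
  if (nrow(obj) != nrow(pop) || any(!is.finite(obj))) {
    abort(sprintf("evaluator returned invalid objectives at generation %d", gen),
          class = "tpmsdesign_evaluator_error")
  }
  obj
}

environmental_selection <- function(obj, np) {
  rc <- rank_and_crowd(obj)
  sel <- integer(0)
  for (idx in rc$fronts) {
    if (length(sel) + length(idx) <= np) {
      sel <- c(sel, idx)
    } else {
      cd <- crowding_distance(obj[idx, , drop = FALSE])
      sel <- c(sel, idx[order(cd, decreasing = TRUE)][seq_len(np - length(sel))])
      break
    }
  }
  sel
}

#' Filter a Pareto front by relative density
#'
#' Retains designs whose predicted relative density lies in the inclusive
#' band `[low, high]` percent — the trabecular-bone-compatible window.
#'
#' @param front Tibble with a `relative_density` column.
#' @param low,high Band bounds in percent (defaults 20 and 40).
#' @return List: `retained` and `rejected` tibbles plus their counts.
#' @export
rd_filter <- function(front, low = 20, high = 40) {
  keep <- front$relative_density >= low & front$relative_density <= high
  list(retained = front[keep, , drop = FALSE],
       rejected = front[!keep, , drop = FALSE],
       n_retained = sum(keep), n_rejected = sum(!keep))
}

#' Optimize one implant-size group against a fitted surrogate
#'
#' Maximizes predicted ultimate stress, energy absorption and SA/VR over
#' the continuous design variables, with bounds taken from the observed
#' variable ranges of the group's designs. The categorical surface type is
#' handled by running NSGA-II once per family (offset seeds), merging the
#' per-family fronts and keeping the non-dominated union. Predicted
#' relative density is attached to every front member for downstream
#' filtering.
#'
#' @param model A fitted `tpms_surrogate` predicting all four targets.
#' @param dataset Design tibble with `size_class` (bounds source).
#' @param group `"small"`, `"medium"` or `"large"`.
#' @param config An [nsga_config()].
#' @param surface_types Families to optimize over.
#' @return A `pareto_front` tibble: design variables, `surface_type`,
#'   objectives, `relative_density`, `size_class`; per-family run reports
#'   in `attr(, "runs")`.
#' @export
optimize_group <- function(model, dataset, group, config = nsga_config(),
                           surface_types = tpms_surfaces()) {
  rows <- dataset[dataset$size_class == group, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("no designs in size group '", group, "'"),
          class = "tpmsdesign_config_error")
  }
  lower <- vapply(rows[DESIGN_VARS], min, numeric(1))
  upper <- vapply(rows[DESIGN_VARS], max, numeric(1))
  degenerate <- upper <= lower
  upper[degenerate] <- lower[degenerate] + 1e-6
  obj_targets <- c("ultimate_stress", "energy_absorption", "sa_vr")

  runs <- purrr::imap(setNames(surface_types, surface_types), function(tp, nm) {
    evaluate <- function(pop) {
      designs <- as_tibble(setNames(as.data.frame(pop), DESIGN_VARS)) %>%
        dplyr::mutate(surface_type = tp)
      as.matrix(predict(model, designs)[obj_targets])
    }
    cfg <- config
    cfg$seed <- config$seed + match(tp, tpms_surfaces())
    run_nsga2(evaluate, lower, upper, cfg)
  })

  merged <- purrr::imap_dfr(runs, function(run, tp) {
    dplyr::bind_cols(
      tibble(surface_type = tp),
      as_tibble(setNames(as.data.frame(run$decisions), DESIGN_VARS)),
      as_tibble(setNames(as.data.frame(run$objectives), obj_targets))
    )
  })
  keep <- fast_non_dominated_sort(as.matrix(merged[obj_targets]))[[1]]
  front <- merged[keep, , drop = FALSE]
  front$relative_density <- predict(model, front)$relative_density
  front$size_class <- group
  structure(front, class = c("pareto_front", class(front)), runs = runs)
}
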