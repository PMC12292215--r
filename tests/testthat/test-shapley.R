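numeric_feats <- c("cell_size_x", "cell_size_y", "cell_size_z", "thickness",
                   "rotation_deg", "height", "diameter")

linear_model <- function(w) {
  function(df) as.numeric(as.matrix(df[names(w)]) %*% w)
}

test_that("exact Shapley matches the closed form for additive models", {
  withr::with_seed(61, {
    w <- setNames(rnorm(7), numeric_feats)
    bg <- random_designs(25)
    inst <- random_designs(1, seed = 99)
    att <- exact_shapley(linear_model(w), inst, bg, features = numeric_feats)
    closed <- w * (unlist(inst[numeric_feats]) -
                     colMeans(as.matrix(bg[numeric_feats])))
    expect_equal(att$phi, unname(closed[att$feature]), tolerance = 1e-9)
    # efficiency to numerical precision
    expect_lt(abs(attr(att, "base_value") + sum(att$phi) -
                    linear_model(w)(inst)), 1e-9)
  })
})

test_that("the dummy and symmetry axioms hold on constructed models", {
  bg <- random_designs(20, seed = 3)
  inst <- random_designs(1, seed = 4)
  # dummy: a feature the model ignores gets exactly zero
  f_partial <- function(df) df$thickness * 100 + df$height
  att <- exact_shapley(f_partial, inst, bg, features = numeric_feats)
  ignored <- setdiff(numeric_feats, c("thickness", "height"))
  expect_true(all(att$phi[att$feature %in% ignored] == 0))
  # symmetry: exchangeable features with equal values get equal phi
  f_sym <- function(df) df$cell_size_x + df$cell_size_y
  inst_sym <- inst
  inst_sym$cell_size_x <- inst_sym$cell_size_y <- 3.7
  bg_sym <- bg
  bg_sym$cell_size_y <- bg_sym$cell_size_x   # identical marginals
  att_sym <- exact_shapley(f_sym, inst_sym, bg_sym, features = numeric_feats)
  expect_equal(att_sym$phi[att_sym$feature == "cell_size_x"],
               att_sym$phi[att_sym$feature == "cell_size_y"],
               tolerance = 1e-12)
  # constant model: all attributions zero
  att0 <- exact_shapley(function(df) rep(3, nrow(df)), inst, bg,
                        features = numeric_feats)
  expect_true(all(att0$phi == 0))
})

test_that("the coalition cap directs large feature sets to the sampler", {
  inst <- random_designs(1)
  inst[paste0("extra", 1:8)] <- as.list(rnorm(8))
  bg <- inst[rep(1, 5), ]
  expect_error(exact_shapley(function(df) rep(0, nrow(df)), inst, bg,
                             features = c(numeric_feats, paste0("extra", 1:8))),
               class = "tpmsdesign_shapley_cap")
})

test_that("sampled Shapley is seeded, consistent with exact, with shrinking errors", {
  withr::with_seed(62, {
    # nonlinear interaction model on 7 features
    f <- function(df) {
      df$thickness * df$height * 3 + sin(df$cell_size_x) * df$diameter +
        df$rotation_deg^2 / 100
    }
    bg <- random_designs(20)
    inst <- random_designs(1, seed = 7)
    ex <- exact_shapley(f, inst, bg, features = numeric_feats)
    sm <- sampled_shapley(f, inst, bg, n_permutations = 300, seed = 5,
                          features = numeric_feats)
    expect_identical(
      sm$phi,
      sampled_shapley(f, inst, bg, n_permutations = 300, seed = 5,
                      features = numeric_feats)$phi)
    expect_true(all(abs(sm$phi - ex$phi) <= 3 * pmax(sm$se, 1e-12)))
    # efficiency holds in expectation and exactly for the estimator's sum
    expect_lt(abs(attr(sm, "base_value") + sum(sm$phi) - mean(f(inst))), 1e-9)
    # Monte-Carlo standard errors shrink roughly as 1/sqrt(n)
    se_small <- mean(sampled_shapley(f, inst, bg, n_permutations = 50,
                                     seed = 1, features = numeric_feats)$se)
    se_big <- mean(sampled_shapley(f, inst, bg, n_permutations = 450,
                                   seed = 1, features = numeric_feats)$se)
    expect_lt(se_big / se_small, 0.6)  # expected 1/3
  })
})

test_that("OFAT curves reproduce identity, constant and monotone structure", {
  ds <- study_dataset()
  ident <- ofat_sensitivity(function(df) df$thickness, ds, "thickness",
                            n_grid = 9)
  expect_equal(ident$response, ident$value)
  flat <- ofat_sensitivity(function(df) rep(2, nrow(df)), ds, "height")
  expect_true(all(flat$response == 2))
  # on the study surrogate, predicted U rises monotonically with thickness
  fit <- study_fit()
  curve <- ofat_sensitivity(fit$model, ds, "thickness", n_grid = 12,
                            target = "ultimate_stress")
  expect_true(all(diff(curve$response) > 0))
  # categorical features are enumerated, not gridded
  types <- ofat_sensitivity(fit$model, ds, "surface_type",
                            target = "ultimate_stress")
  expect_identical(sort(types$value), sort(tpms_surfaces()))
})

test_that("group attribution ranks thickness first for ultimate stress", {
  fit <- study_fit()
  ds <- study_dataset()
  sa <- summary_attributions(fit$model, ds, target = "ultimate_stress",
                             group = "medium", method = "exact",
                             n_background = 40, n_samples = 12, seed = 2)
  expect_identical(sa$ranking$feature[1], "thickness")
  # rankings stable across two seeds of the sampled estimator
  s1 <- summary_attributions(fit$model, ds, target = "ultimate_stress",
                             group = "small", method = "sampled",
                             n_background = 30, n_samples = 8,
                             n_permutations = 40, seed = 11)
  s2 <- summary_attributions(fit$model, ds, target = "ultimate_stress",
                             group = "small", method = "sampled",
                             n_background = 30, n_samples = 8,
                             n_permutations = 40, seed = 12)
  expect_identical(s1$ranking$feature[1], s2$ranking$feature[1])
  expect_identical(s1$ranking$feature[1], "thickness")
})
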