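test_that("the default full-factorial sweep and stability filter reproduce the study counts", {
  designs <- enumerate_designs()
  expect_identical(nrow(designs), 3456L)
  kept <- filter_aspect_ratio(designs)
  expect_identical(nrow(kept), 3024L)
  # partition: retained and removed are disjoint and exhaustive
  removed <- dplyr::anti_join(designs, kept,
                              by = names(designs))
  expect_identical(nrow(kept) + nrow(removed), nrow(designs))
  expect_true(all(removed$height / removed$diameter > 2))
})

test_that("enumeration count equals the product of level counts on random configs", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      cfg <- design_space_config(
        type_levels = sample(tpms_surfaces(), sample(1:3, 1)),
        cell_levels_x = runif(sample(1:3, 1), 2, 5),
        cell_levels_y = runif(sample(1:2, 1), 2, 5),
        cell_levels_z = runif(sample(1:3, 1), 2, 5),
        thickness_levels = runif(sample(1:3, 1), 0.1, 0.5),
        rotation_levels = runif(sample(1:2, 1), 0, 80),
        height_levels = runif(sample(1:3, 1), 5, 20),
        diameter_levels = runif(sample(1:3, 1), 5, 20))
      expected <- prod(vapply(cfg[seq_len(8)], length, integer(1)))
      expect_identical(nrow(enumerate_designs(cfg)), as.integer(expected))
    }
  })
  single <- design_space_config(type_levels = "gyroid", cell_levels_x = 3,
                                cell_levels_y = 3, cell_levels_z = 3,
                                thickness_levels = 0.3, rotation_levels = 0,
                                height_levels = 8, diameter_levels = 5)
  expect_identical(nrow(enumerate_designs(single)), 1L)
})

test_that("size classification follows the small/large precedence rules", {
  expect_identical(as.character(classify_size(8, 5)), "small")
  expect_identical(as.character(classify_size(20, 20)), "large")
  expect_identical(as.character(classify_size(10, 5)), "medium")
  expect_identical(as.character(classify_size(8, 20)), "large")
  # exhaustive and exclusive over a grid
  g <- expand.grid(h = seq(1, 25, by = 0.5), d = seq(1, 25, by = 0.5))
  cls <- classify_size(g$h, g$d)
  expect_false(any(is.na(cls)))
})

test_that("size-class counts per surface family match the study table", {
  ds <- add_size_class(filter_aspect_ratio(enumerate_designs()))
  counts <- table(ds$surface_type, ds$size_class)
  for (tp in tpms_surfaces()) {
    expect_identical(as.integer(counts[tp, ]), c(72L, 504L, 432L))
  }
  pooled <- table(ds$size_class)
  expect_identical(as.integer(pooled), c(216L, 1512L, 1296L))
  expect_identical(sum(pooled), nrow(ds))
})

test_that("feature encoding z-scores numerics, one-hots the type, and inverts", {
  ds <- add_size_class(filter_aspect_ratio(enumerate_designs()))
  enc <- encode_features(ds)
  num <- enc$features[, 1:7]
  expect_true(all(abs(colMeans(num)) < 1e-9))
  expect_true(all(abs(apply(num, 2, var) - 1) < 1e-9))
  onehot <- enc$features[, 8:10]
  expect_true(all(rowSums(onehot) == 1))
  g <- encode_features(ds[ds$surface_type == "gyroid", ][1, ], enc$scaler)
  expect_identical(unname(g$features[, 8:10]), c(1, 0, 0))
  # round trip
  back <- decode_features(enc$features, enc$scaler)
  expect_equal(back$cell_size_x, ds$cell_size_x, tolerance = 1e-12)
  expect_equal(back$diameter, ds$diameter, tolerance = 1e-12)
  expect_identical(back$surface_type, ds$surface_type)
})

test_that("zero-variance features are rejected by name", {
  ds <- enumerate_designs(design_space_config(height_levels = 8))
  err <- tryCatch(fit_feature_scaler(ds), error = function(e) e)
  expect_s3_class(err, "tpmsdesign_scaling_error")
  expect_match(conditionMessage(err), "height")
})

test_that("group summaries match a sort-based quantile oracle", {
  withr::with_seed(31, {
    ds <- random_designs(200) %>% add_size_class() %>%
      dplyr::mutate(prop = rnorm(200))
    gs <- group_summary(ds, "prop")
    # continuous H/D sampling leaves the small class empty: flagged, not fatal
    empty <- gs[gs$n == 0, ]
    expect_true(all(is.na(empty$median)))
    for (g in as.character(unique(ds$size_class))) {
      x <- sort(ds$prop[ds$size_class == g])
      # type-7 quantile by hand: linear interpolation at h = (n-1)p + 1
      q <- function(p) {
        h <- (length(x) - 1) * p + 1
        x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
      }
      row <- gs[gs$size_class == g, ]
      expect_equal(row$q1, q(0.25))
      expect_equal(row$median, q(0.5))
      expect_equal(row$q3, q(0.75))
      expect_identical(row$min, x[1])
      expect_identical(row$max, x[length(x)])
      iqr <- q(0.75) - q(0.25)
      expect_identical(row$n_outliers,
                       sum(x < q(0.25) - 1.5 * iqr | x > q(0.75) + 1.5 * iqr))
    }
  })
})

test_that("constant properties give zero IQR and no outliers", {
  ds <- random_designs(50) %>% add_size_class() %>% dplyr::mutate(prop = 7)
  gs <- group_summary(ds, "prop")
  present <- gs[gs$n > 0, ]
  expect_true(all(present$iqr == 0))
  expect_true(all(present$n_outliers == 0))
})
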