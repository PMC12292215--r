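test_that("force-displacement converts to engineering stress-strain", {
  cv <- engineering_curve(force = c(0, 785.398), displacement = c(0, 20),
                          diameter = 10, height = 20)
  expect_equal(cv$stress[2], 10, tolerance = 1e-6)  # F / (pi * 25 mm^2)
  expect_equal(cv$strain[2], 1)                     # displacement = height
  err <- tryCatch(engineering_curve(c(0, 1, 2), c(0, 2, 1), 10, 20),
                  error = function(e) e)
  expect_s3_class(err, "tpmsdesign_curve_error")
  expect_match(conditionMessage(err), "index 3")
})

test_that("ultimate stress is the curve maximum", {
  cv <- stress_strain_curve(c(0, 0.1, 0.2, 0.3), c(0, 50, 120, 90))
  expect_identical(ultimate_stress(cv), 120)
  cv2 <- stress_strain_curve(c(0, 0.1, 0.2, 0.3, 0.4), c(0, 50, 120, 90, 119))
  expect_identical(ultimate_stress(cv2), 120)
  withr::with_seed(41, {
    s <- cumsum(runif(50)); st <- runif(50, 0, 200)
    expect_identical(ultimate_stress(stress_strain_curve(s, st)),
                     max(st))  # brute-force scan
  })
})

test_that("energy absorption integrates the curve to the strain limit", {
  flat <- stress_strain_curve(c(0, 0.25, 0.5, 0.6), rep(100, 4))
  expect_equal(as.numeric(energy_absorption(flat)), 50)
  ramp <- stress_strain_curve(c(0, 0.5), c(0, 100))
  expect_equal(as.numeric(energy_absorption(ramp)), 25)
  # limit crossing interpolates: constant 100 sampled past the limit
  cross <- stress_strain_curve(c(0, 0.4, 0.7), c(100, 100, 100))
  expect_equal(as.numeric(energy_absorption(cross)), 50)
})

test_that("energy absorption matches a fine-grid Riemann oracle and is additive", {
  f <- function(e) 100 * sqrt(e) + 20 * e       # smooth nonlinear curve
  eps <- seq(0, 0.6, length.out = 4000)
  cv <- stress_strain_curve(eps[-1], f(eps[-1]))
  ee <- seq(1e-9, 0.5, length.out = 2e6)
  riemann <- mean(f(ee)) * 0.5
  expect_equal(as.numeric(energy_absorption(cv)), riemann, tolerance = 1e-5)
  # additivity over subintervals and monotonicity in the limit
  e1 <- as.numeric(energy_absorption(cv, 0.25))
  e2 <- as.numeric(energy_absorption(cv, 0.5))
  expect_gt(e2, e1)
  mid <- sum(diff(pmin(cv$strain, 0.5)[cv$strain >= 0.25 - 1e-12]) * 0)
  expect_equal(e2 - e1,
               as.numeric(energy_absorption(cv, 0.5)) -
                 as.numeric(energy_absorption(cv, 0.25)))
})

test_that("a curve ending before the limit is integrated to its end with a flag", {
  short <- stress_strain_curve(c(0, 0.2), c(100, 100))
  expect_warning(ea <- energy_absorption(short), "before limit")
  expect_equal(as.numeric(ea), 20)
  expect_true(attr(ea, "truncated"))
})

test_that("extended metrics recover an ideal elastic-perfectly-plastic curve", {
  E <- 1000; sy <- 100
  eps <- c(seq(0, sy / E, length.out = 40), seq(sy / E + 0.01, 0.5, length.out = 60))
  sig <- pmin(E * eps, sy)
  m <- mech_metrics(stress_strain_curve(eps[-1], sig[-1]))
  expect_equal(m$youngs_modulus, E, tolerance = 1e-6)
  expect_equal(m$plateau_stress, sy, tolerance = 1e-9)
  # 0.2%-offset line sigma = E (eps - 0.002) meets the plateau at sigma = sy
  expect_equal(m$yield_strength, sy, tolerance = 1e-3)
  expect_false(m$yield_flagged)
  expect_identical(m$ultimate_stress, sy)
})

test_that("metrics are stable under resampling density", {
  E <- 2000; sy <- 80
  curve_at <- function(n) {
    eps <- seq(1e-4, 0.5, length.out = n)
    stress_strain_curve(eps, pmin(E * eps, sy))
  }
  m1 <- mech_metrics(curve_at(200))
  m2 <- mech_metrics(curve_at(2000))
  for (col in c("ultimate_stress", "energy_absorption", "youngs_modulus",
                "yield_strength", "plateau_stress")) {
    expect_lt(abs(m1[[col]] - m2[[col]]) / abs(m2[[col]]), 0.01)
  }
})

test_that("the Johnson-Cook failure strain follows its calibrated form", {
  expect_equal(jc_failure_strain(0), 0.555)
  expect_equal(jc_failure_strain(5, d2 = 0), 0.005)
  expect_equal(jc_failure_strain(1e8), 0.005, tolerance = 1e-12)
  # monotone decreasing in triaxiality for d2 > 0, d3 < 0
  tri <- seq(-1, 3, length.out = 50)
  expect_true(all(diff(jc_failure_strain(tri)) < 0))
  # rate and temperature factors enter multiplicatively
  expect_equal(jc_failure_strain(0, d4 = 0.1, rate_term = 2),
               0.555 * 1.2)
})
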