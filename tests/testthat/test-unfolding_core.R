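test_that("unfolded_fraction maps endpoints and midpoint correctly", {
  curve <- unfolding_curve("temperature_C", c(20, 40, 60, 80),
                           c(10, 60, 110, 60), "I")
  f <- unfolded_fraction(curve, F_n = 10, F_d = 110)
  expect_equal(f$f_u, c(0, 0.5, 1, 0.5))
  expect_error(unfolded_fraction(curve, 10, 10), "degenerate")
  # raw values retained outside [0, 1]; clip only on request
  c2 <- unfolding_curve("temperature_C", c(20, 40), c(5, 120), "I")
  expect_equal(unfolded_fraction(c2, 10, 110)$f_u, c(-0.05, 1.1))
  expect_equal(unfolded_fraction(c2, 10, 110, clip = TRUE)$f_u, c(0, 1))
})

test_that("fit_transition recovers generator truth and exact symmetry", {
  # noise-free log-ratio observable of the thermal generator (midpoint set
  # to 54.57 as generator truth)
  tr <- spectral_truth("one_step", midpoints = 54.57, steepness = 2)
  s <- generate_denaturation_series(tr, condition_values = seq(20, 95, 5))
  fit <- fit_transition(log_ratio_curve(s))
  expect_lt(abs(fit$midpoint - 54.57), 0.01)
  expect_gte(fit$n_points, 4)
  # symmetric exact sigmoid -> midpoint equals x0, baselines exact
  curve <- make_sigmoid_curve(seq(30, 70, 2.5), A = 3, B = 17, x0 = 50,
                              k = 3)
  fit2 <- fit_transition(curve)
  expect_equal(fit2$midpoint, 50, tolerance = 1e-8)
  expect_equal(fit2$baseline_native, 3, tolerance = 1e-6)
  expect_equal(fit2$baseline_denatured, 17, tolerance = 1e-6)
  expect_equal(fit2$steepness, 3, tolerance = 1e-6)
})

test_that("fit_transition rejects degenerate inputs", {
  expect_error(fit_transition(unfolding_curve("pH", c(7, 6, 5, 4),
                                              rep(2, 4), "I")),
               "constant")
  expect_error(fit_transition(unfolding_curve("pH", c(7, 6, 5),
                                              c(1, 2, 3), "I")),
               "< 4 points")
  # plateau-noise guard: endpoint scatter comparable to the full range
  # (range <= 3x the plateau MAD) must be rejected before fitting
  x <- seq(20, 90, 10)
  y <- c(5.5, 4.5, 5, 5, 5, 5, 4.5, 5.5)
  expect_error(fit_transition(unfolding_curve("temperature_C", x, y, "I")),
               "plateau noise")
})

test_that("fit is equivariant under y-affine maps and x reversal", {
  curve <- make_sigmoid_curve(seq(20, 95, 5), A = 1, B = 0.2, x0 = 54,
                              k = 2.4)
  base <- fit_transition(curve)
  for (ab in list(c(37, 5), c(-2.5, -11), c(0.001, 0))) {
    tc <- unfolding_curve(curve$axis_kind, curve$x,
                          ab[1] * curve$y + ab[2], "I")
    fit <- fit_transition(tc)
    expect_equal(fit$midpoint, base$midpoint, tolerance = 1e-8)
    expect_equal(fit$steepness, base$steepness, tolerance = 1e-8)
  }
  rev_curve <- unfolding_curve(curve$axis_kind, rev(curve$x), rev(curve$y),
                               "I")
  fit_rev <- fit_transition(rev_curve)
  expect_equal(fit_rev$midpoint, base$midpoint, tolerance = 1e-10)
  expect_equal(fit_rev$baseline_native, base$baseline_native,
               tolerance = 1e-8)
})

test_that("pH-axis fits report native baseline at high pH, negative slope", {
  # acid unfolding: signal low (native) at pH 7, high (unfolded) at pH 1
  x <- seq(7, 1, -0.25)
  y <- 1 + (9 - 1) / (1 + exp((x - 3.9) / 0.3))  # rises as pH drops
  fit <- fit_transition(unfolding_curve("pH", x, y, "I"))
  expect_equal(fit$midpoint, 3.9, tolerance = 1e-6)
  expect_lt(fit$steepness, 0)
  expect_equal(fit$baseline_native, 1, tolerance = 1e-6)
  expect_equal(fit$baseline_denatured, 9, tolerance = 1e-6)
})

test_that("two-step segmental fits recover both generator midpoints", {
  # acid pair (3.87, 2.43) used as generator truth
  tr <- spectral_truth("two_step", midpoints = c(3.87, 2.43),
                       steepness = c(0.25, 0.2))
  s <- generate_denaturation_series(tr, axis_kind = "pH",
                                    condition_values = seq(7, 1, -0.2))
  fits <- fit_two_step(log_ratio_curve(s), segment_scheme(3.0))
  expect_named(fits, c("segment1", "segment2"))
  expect_lt(abs(fits$segment1$midpoint - 3.87), 0.02)
  expect_lt(abs(fits$segment2$midpoint - 2.43), 0.02)
  # midpoints ordered along the unfolding direction (decreasing pH)
  expect_gt(fits$segment1$midpoint, fits$segment2$midpoint)

  # thermal pair on an ascending axis
  tr2 <- spectral_truth("two_step", midpoints = c(54.57, 71.54),
                        steepness = c(2, 2))
  s2 <- generate_denaturation_series(tr2,
                                     condition_values = seq(20, 95, 2.5))
  fits2 <- fit_two_step(log_ratio_curve(s2), segment_scheme(60))
  expect_lt(abs(fits2$segment1$midpoint - 54.57), 0.02)
  expect_lt(abs(fits2$segment2$midpoint - 71.54), 0.02)
})

test_that("empty scheme reduces exactly to fit_transition", {
  curve <- make_sigmoid_curve(seq(20, 95, 5), 0.1, 0.9, 55, 3)
  direct <- fit_transition(curve)
  via_scheme <- fit_two_step(curve, segment_scheme())
  expect_identical(via_scheme$segment1$midpoint, direct$midpoint)
  expect_identical(via_scheme$segment1$residual_norm, direct$residual_norm)
})

test_that("breakpoints outside the data range are rejected", {
  curve <- make_sigmoid_curve(seq(20, 95, 5), 0.1, 0.9, 55, 3)
  expect_error(fit_two_step(curve, segment_scheme(100)), "inside")
  expect_error(fit_two_step(curve, segment_scheme(20)), "inside")
})

test_that("normalize_segment maps plateaus to 0/1 and round-trips", {
  truth <- fraction_curve("temperature_C", seq(20, 95, 5),
                          1 / (1 + exp(-(seq(20, 95, 5) - 55) / 3)))
  # synthesize an observable with known baselines from the fraction curve
  obs <- unfolding_curve("temperature_C", truth$x, 200 + 700 * truth$f_u,
                         "I")
  fit <- fit_transition(obs)
  frac <- normalize_segment(obs, fit)
  expect_equal(frac$f_u, truth$f_u, tolerance = 1e-6)
  expect_lt(abs(frac$f_u[1]), 1e-5)                    # native plateau
  expect_lt(abs(frac$f_u[length(frac$f_u)] - 1), 1e-3) # denatured plateau
})

test_that("midpoint recovery is unbiased with near-nominal coverage", {
  # reduced-size version of the replicate study (full version in the
  # acceptance suite): 60 noisy replicates at 2% amplitude noise
  x <- seq(20, 95, 5)
  truth <- 54.57
  clean <- 0.2 + 0.8 / (1 + exp(-(x - truth) / 2.3))
  set.seed(11)
  mids <- ses <- numeric(60)
  for (i in 1:60) {
    y <- clean + rnorm(length(x), sd = 0.02 * 0.8)
    f <- fit_transition(unfolding_curve("temperature_C", x, y, "I"))
    mids[i] <- f$midpoint; ses[i] <- f$midpoint_se
  }
  expect_lt(abs(mean(mids) - truth), mean(ses))
  covered <- abs(mids - truth) <= 1.96 * ses
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})

test_that("fit results serialize to JSON records", {
  curve <- make_sigmoid_curve(seq(20, 95, 5), 0.1, 0.9, 55, 3)
  js <- sigmoid_fits_json(fit_transition(curve))
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$segment1$midpoint, 55, tolerance = 1e-6)
  expect_true(all(c("steepness", "baseline_native", "residual_norm",
                    "segment") %in% names(rec$segment1)))
})
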