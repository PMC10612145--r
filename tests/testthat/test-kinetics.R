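test_that("pseudo-first-order fit recovers an exact exponential", {
  tr <- simulate_kinetic_trace(0.01, amplitude = 0.1, offset = 0.02,
                               t_grid = seq(0, 600, by = 10))
  f <- fit_pseudo_first_order(tr)
  expect_true(f$converged)
  expect_lt(abs(f$parameters["k_obsd"] - 0.01) / 0.01, 1e-6)
  expect_equal(unname(f$parameters["amplitude"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(f$parameters["offset"]), 0.02, tolerance = 1e-5)
  # half-life identity: k * t_half = ln 2
  a_half <- 0.02 + 0.05
  t_half <- -log(1 - 0.5) / unname(f$parameters["k_obsd"])
  expect_equal(unname(f$parameters["k_obsd"]) * t_half, log(2),
               tolerance = 1e-6)
  expect_equal(0.02 + 0.1 * (1 - exp(-0.01 * t_half)), a_half,
               tolerance = 1e-6)
})

test_that("rate is invariant to uniform signal scaling", {
  tr <- simulate_kinetic_trace(0.004, amplitude = 0.2, offset = 0.01,
                               t_grid = seq(0, 1200, by = 20))
  f1 <- fit_pseudo_first_order(tr)
  tr2 <- kinetic_trace(tr$time, tr$signal * 37)
  f2 <- fit_pseudo_first_order(tr2)
  expect_equal(unname(f1$parameters["k_obsd"]),
               unname(f2$parameters["k_obsd"]), tolerance = 1e-8)
  expect_equal(unname(f2$parameters["amplitude"]),
               37 * unname(f1$parameters["amplitude"]), tolerance = 1e-6)
})

test_that("flat traces are flagged, not fitted", {
  tr <- kinetic_trace(seq(0, 100, by = 10), rep(0.3, 11))
  f <- fit_pseudo_first_order(tr)
  expect_false(f$converged)
  expect_match(f$flags, "flat")
  expect_error(kinetic_trace(c(0, 1, 1, 2, 3), 1:5), "strictly increasing")
  expect_error(kinetic_trace(1:3, 1:3), ">= 5")
})

test_that("breakpoint detection finds exact intersections", {
  x <- seq(0, 8, by = 0.5)
  y <- ifelse(x < 6, 10 - 1.5 * x, 1)
  f <- titration_endpoints(data.frame(x = x, y = y), n_breaks = 1)
  expect_equal(unname(f$parameters["knot1"]), 6, tolerance = 1e-6)
  expect_equal(unname(f$parameters["slope1"]), -1.5, tolerance = 1e-5)
  # two-endpoint profile: steep drop to 4 eq, slow decline to 6, flat after
  y2 <- ifelse(x < 4, 10 - 2 * x, ifelse(x < 6, 2 - 0.5 * (x - 4), 1))
  f2 <- titration_endpoints(data.frame(x = x, y = y2), n_breaks = 2)
  expect_equal(unname(f2$parameters[c("knot1", "knot2")]), c(4, 6),
               tolerance = 1e-6)
  # more knots can only lower the objective
  expect_lte(f2$residual_norm,
             titration_endpoints(data.frame(x = x, y = y2), 1)$residual_norm +
               1e-12)
})

test_that("a single line is flagged unidentifiable", {
  x <- seq(0, 8, by = 1)
  f <- titration_endpoints(data.frame(x = x, y = 2 - 0.3 * x), n_breaks = 1)
  expect_match(f$flags, "unidentifiable")
  expect_error(titration_endpoints(data.frame(x = 1:3, y = 1:3), 1),
               "need >=")
})

test_that("chelator-affinity rate regression is ordinary least squares", {
  # collinear points ("perfect fit" note from the underlying lm is expected)
  f0 <- suppressWarnings(chelator_rate_regression(
    data.frame(chelator_pkd = c(5, 6, 7), log10_k_obsd = c(-3, -2.5, -2))))
  expect_equal(unname(f0$parameters["r_squared"]), 1, tolerance = 1e-12)
  # chelator ladder from weak to moderate affinity
  f <- chelator_rate_regression(
    data.frame(chelator_pkd = c(5.1, 6.9, 8.4),
               log10_k_obsd = c(-3, -2.1, -1.3)))
  expect_equal(unname(f$parameters["slope"]), 2.81 / 5.46, tolerance = 1e-6)
  expect_error(chelator_rate_regression(
    data.frame(chelator_pkd = c(5, 5, 5), log10_k_obsd = c(-3, -2, -1))),
    "rank deficient")
  expect_error(chelator_rate_regression(
    data.frame(chelator_pkd = c(5, 6), log10_k_obsd = c(-3, -2))),
    ">= 3")
})
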