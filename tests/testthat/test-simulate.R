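test_that("the same seed reproduces every simulated dataset exactly", {
  reg <- fixture_registry()
  xl <- reg$proteins$XlMT
  ns <- noise_spec(0.02, 99)
  a <- simulate_znaf_transfer_isotherm(xl, 5e-7, 10^seq(-7, -5.5, by = 0.25),
                                       reg$probes$znaf, noise = ns)
  b <- simulate_znaf_transfer_isotherm(xl, 5e-7, 10^seq(-7, -5.5, by = 0.25),
                                       reg$probes$znaf, noise = ns)
  expect_identical(a, b)
  t1 <- simulate_ph_titration(4.7, 2, c(0, 0.4), seq(3, 7, by = 0.25),
                              noise = ns)
  t2 <- simulate_ph_titration(4.7, 2, c(0, 0.4), seq(3, 7, by = 0.25),
                              noise = ns)
  expect_identical(t1, t2)
  k1 <- simulate_kinetic_trace(0.01, noise = ns)
  k2 <- simulate_kinetic_trace(0.01, noise = ns)
  expect_identical(k1, k2)
  # different seed, different data
  k3 <- simulate_kinetic_trace(0.01, noise = noise_spec(0.02, 100))
  expect_false(identical(k1$signal, k3$signal))
})

test_that("zero-noise simulations are exact, monotone forward curves", {
  reg <- fixture_registry()
  xl <- reg$proteins$XlMT
  iso <- simulate_znaf_transfer_isotherm(xl, 5e-7,
                                         10^seq(-7.3, -5.3, by = 0.2),
                                         reg$probes$znaf)
  expect_true(all(diff(iso$transferred_eq) > 0))   # more probe, more transfer
  expect_true(all(diff(iso$pzn) > 0))              # and lower free Zn
  tit <- simulate_apo_titration(xl, 5e-7, 3e-6, seq(0, 8, by = 0.5),
                                reg$probes$znaf)
  expect_true(is.na(tit$pzn[1]))                   # apo sentinel at r = 0
  expect_true(all(diff(tit$fluorescence[-1]) > 0))
  # pH curve is exactly the Hill form
  g <- seq(3, 7, by = 0.5)
  tt <- simulate_ph_titration(4.73, 2, c(0.1, 0.5), g)
  expect_equal(tt$absorbance,
               0.1 + 0.4 / (1 + 10^(2 * (4.73 - g))), tolerance = 1e-12)
  # kinetic trace is exactly exponential
  tg <- seq(0, 500, by = 50)
  tr <- simulate_kinetic_trace(0.01, 0.2, 0.05, tg)
  expect_equal(tr$signal, 0.05 + 0.2 * (1 - exp(-0.01 * tg)),
               tolerance = 1e-12)
})

test_that("competition transfer responds to the probe amount", {
  reg <- fixture_registry()
  sm <- reg$proteins$SmtA
  none <- simulate_par_transfer(sm, 1e-6, 0)
  expect_equal(none$transferred_eq, 0)
  low <- simulate_par_transfer(sm, 1e-6, 2e-5)
  high <- simulate_par_transfer(sm, 1e-6, 2e-4)
  expect_gt(high$transferred_eq, low$transferred_eq)
  expect_lt(high$transferred_eq, sm$n_sites)
  # bacterial protein transfers far less than an animal one
  xl_t <- simulate_par_transfer(reg$proteins$XlMT, 1e-6, 2e-4)$transferred_eq
  expect_gt(xl_t / high$transferred_eq, 3)
})

test_that("each simulator is inverted by its paired estimator", {
  reg <- fixture_registry()
  # competition transfer -> average per-site constant
  m <- independent_sites_model("w", rep(10.5, 4))
  obs <- simulate_par_transfer(m, 1e-6, 2e-4)
  expect_equal(unname(average_persite_kd(obs)$parameters), 10.5,
               tolerance = 0.01 / 10.5)
  # buffer CD -> corrected Hill fit
  cdm <- independent_sites_model("cd", c(14.3, 14.3))
  chs <- reg$chelators[c("HEDTA", "EDTA", "TPEN")]
  pts <- simulate_buffer_cd(cdm, chs, seq(0.05, 0.85, by = 0.2), 2e-5,
                            5e-4, c(0, -25))
  fb <- fit_hill_buffer(pts, chs, 2e-5, 2)
  expect_equal(unname(fb$parameters["neg_log_kd_av"]), 14.3,
               tolerance = 0.05 / 14.3)
  # apo titration pzn is consistent with the recorded fluorescence
  tit <- simulate_apo_titration(reg$proteins$MacMT3, 5e-7, 2e-6,
                                seq(0.5, 5, by = 0.5), reg$probes$znaf)
  cal <- fluorescence_calibration(0, 1, reg$probes$znaf)
  expect_equal(free_zinc_from_fluorescence(tit$fluorescence, cal),
               10^(-tit$pzn), tolerance = 1e-9)
})

test_that("simulators validate their grids", {
  reg <- fixture_registry()
  expect_error(simulate_znaf_transfer_isotherm(reg$proteins$XlMT, 5e-7,
                                               c(2e-6, 1e-6),
                                               reg$probes$znaf),
               "increasing")
  expect_error(simulate_apo_titration(reg$proteins$XlMT, 5e-7, 3e-6,
                                      c(1, 1), reg$probes$znaf),
               "increasing")
  expect_error(simulate_kinetic_trace(-1), "k_obsd > 0")
})
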