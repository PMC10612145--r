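test_that("average per-site constant reproduces published competition values", {
  # printed transfers at 1 uM protein, 200 uM competitor
  bcr <- average_persite_kd(transfer_observation(0.98, 1e-6, 2e-4, 6))
  expect_equal(unname(bcr$parameters["neg_log_kd_av"]), 11.47,
               tolerance = 0.05 / 11.47)
  xl <- average_persite_kd(transfer_observation(1.27, 1e-6, 2e-4, 7))
  expect_equal(unname(xl$parameters["neg_log_kd_av"]), 11.29,
               tolerance = 0.05 / 11.29)
  # at t = x/2 the empty/filled ratio is 1, so Kd_av = free Zn exactly
  half <- average_persite_kd(transfer_observation(3, 1e-6, 2e-4, 6))
  expect_equal(10^(-unname(half$parameters)), half$free_zn,
               tolerance = 1e-12)
  # unbounded estimates are flagged, not returned as numbers
  ub <- average_persite_kd(transfer_observation(0, 1e-6, 2e-4, 6))
  expect_false(ub$converged)
})

test_that("stepwise transfer model matches published one-step constants", {
  ec1 <- stepwise_kd_from_transfer(transfer_observation(0.93, 1e-6, 2e-4, 6),
                                   n_steps = 1)
  expect_equal(unname(ec1$parameters["neg_log_kd1"]), 9.67,
               tolerance = 0.05 / 9.67)
  smta <- stepwise_kd_from_transfer(transfer_observation(0.05, 1e-6, 2e-4, 4),
                                    n_steps = 1)
  expect_equal(unname(smta$parameters["neg_log_kd1"]), 13.36,
               tolerance = 0.05 / 13.36)
  # closed-form identity at t = 1/2: Kd1 = z exactly
  h <- stepwise_kd_from_transfer(transfer_observation(0.5, 1e-6, 2e-4, 6),
                                 n_steps = 1)
  expect_equal(10^(-unname(h$parameters)), h$free_zn, tolerance = 1e-12)
})

test_that("multi-step bisection agrees with the closed form at n_steps = 1", {
  set.seed(5)
  for (t in runif(6, 0.05, 0.95)) {
    obs <- transfer_observation(t, 1e-6, 2e-4, 6)
    a <- stepwise_kd_from_transfer(obs, n_steps = 1)
    z <- free_zinc_from_par(t * 1e-6, 2e-4)
    expect_equal(10^(-unname(a$parameters)), z * t / (1 - t),
                 tolerance = 1e-9)
  }
  bad <- stepwise_kd_from_transfer(transfer_observation(2.5, 1e-6, 2e-4, 6),
                                   n_steps = 2)
  expect_false(bad$converged)
})

test_that("forward-simulated transfer returns the generating constant", {
  # identical independent weak sites: Kd_av must equal the input Kd
  m <- independent_sites_model("w6", rep(11, 6))
  obs <- simulate_par_transfer(m, 1e-6, 2e-4)
  est <- average_persite_kd(obs)
  expect_equal(unname(est$parameters["neg_log_kd_av"]), 11,
               tolerance = 0.01 / 11)
})

test_that("weak-site isotherm fits recover their generating constants", {
  reg <- fixture_registry()
  # two distinct weak sites, generated through the full equilibrium
  sub <- independent_sites_model("pair", c(9.37, 7.74))
  iso <- simulate_znaf_transfer_isotherm(sub, 5e-7,
                                         10^seq(-7.3, -5.3, by = 0.1),
                                         reg$probes$znaf)
  f2 <- fit_weak_sites_znaf(iso, n_weak = 2, protein_total = 5e-7)
  expect_equal(unname(f2$parameters), c(9.37, 7.74), tolerance = 0.05 / 8)
  # exact single-site data leaves no residual
  pzn <- seq(10, 6, by = -0.25)
  t1 <- 1 / (1 + 10^(8 - pzn))
  f1 <- fit_weak_sites_znaf(data.frame(pzn = pzn, transferred_eq = t1),
                            n_weak = 1)
  expect_lt(f1$residual_norm, 1e-12)
  expect_equal(unname(f1$parameters["pkd1"]), 8, tolerance = 1e-6)
  # cooperative release of three sites sharing one constant
  tc <- 3 / (1 + 10^(3 * (6.75 - pzn)))
  fc <- fit_weak_sites_znaf(data.frame(pzn = pzn, transferred_eq = tc),
                            cooperative = TRUE, n_coop = 3)
  expect_equal(unname(fc$parameters["pkd"]), 6.75, tolerance = 0.05 / 6.75)
})

test_that("degenerate isotherms are flagged instead of fitted", {
  flat <- data.frame(pzn = seq(12, 11, by = -0.2),
                     transferred_eq = rep(0, 6))
  f <- fit_weak_sites_znaf(flat, n_weak = 1)
  expect_false(f$converged)
})

test_that("pH titration Hill fit recovers exact synthetic parameters", {
  tit <- simulate_ph_titration(4.73, 2, c(0, 0.4), seq(2.5, 8, by = 0.25))
  f <- fit_hill_ph(tit)
  expect_true(f$converged)
  expect_equal(unname(f$parameters["pka"]), 4.73, tolerance = 1e-6)
  expect_equal(unname(f$parameters["n"]), 2, tolerance = 1e-5)
  # midpoint identity at n = 1
  tit1 <- simulate_ph_titration(5, 1, c(0.1, 0.5), seq(2, 8, by = 0.5))
  mid <- tit1$absorbance[tit1$ph == 5]
  expect_equal(mid, 0.3, tolerance = 1e-12)
  # fixed-n variant
  ffix <- fit_hill_ph(tit, fix_n = 2)
  expect_equal(unname(ffix$parameters["pka"]), 4.73, tolerance = 1e-6)
  expect_error(fit_hill_ph(tit[1:4, ]), ">= 6")
})

test_that("metal-buffer Hill fit corrects for chelator depletion", {
  reg <- fixture_registry()
  chs <- reg$chelators[c("HEDTA", "EDTA", "TPEN")]
  # negligible depletion: result equals the uncorrected Hill fit
  cdm <- independent_sites_model("cd", c(14.68, 14.68))
  tiny <- simulate_buffer_cd(cdm, chs, seq(0.05, 0.85, by = 0.1), 1e-9,
                             5e-4, c(0, -30))
  fb0 <- fit_hill_buffer(tiny, chs, 1e-9, 2)
  plain <- minpack.lm::nlsLM(
    ellipticity ~ e_apo + (e_holo - e_apo) / (1 + 10^(n * (pzn_initial - pk))),
    data = tiny, start = list(e_apo = 0, e_holo = -30, pk = 14.7, n = 1))
  expect_equal(unname(fb0$parameters["neg_log_kd_av"]),
               unname(coef(plain)["pk"]), tolerance = 1e-4)
  # realistic protein load: depletion matters and is corrected away
  pts <- simulate_buffer_cd(cdm, chs, seq(0.05, 0.85, by = 0.1), 2e-5,
                            5e-4, c(0, -30))
  fb <- fit_hill_buffer(pts, chs, 2e-5, 2)
  expect_equal(unname(fb$parameters["neg_log_kd_av"]), 14.68,
               tolerance = 0.05 / 14.68)
  expect_gt(fb$iterations, 1)
  # transfer exceeding the buffered pool is an input error
  bad <- pts
  bad$chelator_total <- 1e-7
  bad$zn_fraction <- 0.05
  expect_error(fit_hill_buffer(bad, chs, 2e-5, 2), "pool")
})
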