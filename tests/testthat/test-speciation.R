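test_that("species fractions match the closed-form Adair weights", {
  m1 <- binding_model("one", 9)
  expect_equal(species_fractions_at_free_zn(m1, 1e-9), c(0.5, 0.5))
  # apo limit
  xl <- fixture_registry()$proteins$XlMT
  fr <- species_fractions_at_free_zn(xl, 1e-20)
  expect_gt(fr[1], 1 - 1e-6)
  expect_error(species_fractions_at_free_zn(m1, 0), "positive")
  # independent recomputation at one point
  z <- 10^-8.5
  lw <- c(0, cumsum(xl$pkd_steps) + seq_len(7) * log10(z))
  w <- 10^(lw - max(lw))
  expect_equal(species_fractions_at_free_zn(xl, z), w / sum(w),
               tolerance = 1e-12)
  # the hexa-loaded species dominates at pZn 8.5
  expect_equal(which.max(species_fractions_at_free_zn(xl, z)), 7L)  # Zn6
})

test_that("fractions are normalized over huge free-Zn and affinity ranges", {
  set.seed(11)
  for (k in 1:25) {
    n <- sample(1:9, 1)
    m <- binding_model("r", sort(runif(n, 5, 16), decreasing = TRUE))
    z <- 10^runif(6, -20, -1)
    fr <- species_fractions_at_free_zn(m, z)
    expect_lt(max(abs(rowSums(fr) - 1)), 1e-9)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("mean occupancy is the Adair binding curve", {
  m1 <- binding_model("one", 9)
  expect_equal(mean_occupancy(m1, 1e-9), 0.5)
  xl <- fixture_registry()$proteins$XlMT
  expect_equal(mean_occupancy(xl, 1e-3), 7, tolerance = 1e-4)
  # near six at pZn 8.5, by independent summation
  z <- 10^-8.5
  lw <- c(0, cumsum(xl$pkd_steps) + seq_len(7) * log10(z))
  w <- 10^(lw - max(lw))
  expect_equal(mean_occupancy(xl, z), sum((0:7) * w) / sum(w),
               tolerance = 1e-12)
  expect_equal(mean_occupancy(xl, z), 6, tolerance = 0.1)
  # strictly increasing in free Zn
  zz <- 10^seq(-16, -4, by = 0.25)
  expect_true(all(diff(mean_occupancy(xl, zz)) > 0))
})

test_that("speciation over pZn is the closed-form logistic family", {
  m1 <- binding_model("one", 9)
  pr <- speciation_vs_pzn(m1, c(8, 9, 10))
  expect_equal(unname(pr$fractions[, "Zn1"]),
               c(1 / 1.1, 0.5, 0.1 / 1.1), tolerance = 1e-3)
  expect_error(speciation_vs_pzn(m1, numeric(0)), "empty")
  expect_error(speciation_vs_pzn(m1, c(8, 10, 9)), "monotone")
  sm <- fixture_registry()$proteins$SmtA
  g <- seq(8, 17, by = 0.01)
  pr2 <- speciation_vs_pzn(sm, g)
  expect_lt(max(abs(rowSums(pr2$fractions) - 1)), 1e-9)
  peak <- g[which.max(pr2$fractions[, "Zn3"])]
  expect_equal(peak, 12.05, tolerance = 0.06)
})

test_that("speciation over Zn/protein ratio solves the full mass balance", {
  m <- binding_model("t", 12)
  pr <- speciation_vs_ratio(m, 1e-6, c(0, 2))
  expect_equal(unname(pr$fractions[1, ]), c(1, 0))          # all apo
  expect_equal(pr$free_zn[2], 1e-6, tolerance = 1e-3)       # excess Zn
  expect_equal(unname(pr$fractions[2, "Zn1"]), 1, tolerance = 1e-5)
  xl <- fixture_registry()$proteins$XlMT
  pr4 <- speciation_vs_ratio(xl, 1e-6, 4)
  expect_equal(unname(which.max(pr4$fractions[1, ])), 5L)   # Zn4 modal
})

test_that("species peaks sit where mean occupancy crosses the index", {
  msep <- binding_model("sep", c(12, 8))
  expect_equal(peak_pzn(msep, 1)$pzn, 10, tolerance = 1e-3)
  reg <- fixture_registry()
  expect_equal(peak_pzn(reg$proteins$XlMT, 6)$pzn, 8.5, tolerance = 0.1)
  expect_equal(peak_pzn(reg$proteins$SmtA, 3)$pzn, 12.1, tolerance = 0.1)
  # terminal species have no interior maximum
  expect_identical(peak_pzn(msep, 0), list(pzn = Inf, interior = FALSE))
  expect_identical(peak_pzn(msep, 2), list(pzn = -Inf, interior = FALSE))
  expect_error(peak_pzn(msep, 3), "species_index")
})

test_that("well-separated steps put the peak at the midpoint", {
  set.seed(3)
  for (k in 1:10) {
    p1 <- runif(1, 11, 15)
    p2 <- p1 - runif(1, 3, 6)
    m <- binding_model("s", c(p1, p2))
    expect_equal(peak_pzn(m, 1)$pzn, (p1 + p2) / 2, tolerance = 0.01)
  }
})

test_that("buffering window matches the logistic width and is monotone", {
  m1 <- binding_model("one", 9)
  w <- buffering_window(m1, 0.9)
  expect_equal(unname(w), c(9 - log10(9), 9 + log10(9)), tolerance = 1e-4)
  w80 <- buffering_window(m1, 0.8)
  expect_gt(w80[["pzn_low"]], w[["pzn_low"]])
  expect_lt(w80[["pzn_high"]], w[["pzn_high"]])
  # cyanobacterial model: compare against a dense-grid evaluation of the
  # occupancy crossings, and check overlap with its pZn 9-14 buffering zone
  sm <- fixture_registry()$proteins$SmtA
  ws <- buffering_window(sm, 0.95)
  g <- seq(8, 18, by = 1e-4)
  occ <- mean_occupancy(sm, 10^(-g))
  expect_equal(ws[["pzn_low"]], g[which.max(occ < 0.95 * 4)],
               tolerance = 1e-3)
  expect_equal(ws[["pzn_high"]], g[which.max(occ < 0.05 * 4)],
               tolerance = 1e-3)
  expect_gt(ws[["pzn_low"]], 9)
  expect_lt(ws[["pzn_low"]], 14)
})

test_that("speciation profiles export as tidy tables", {
  m <- binding_model("t", c(10, 8))
  pr <- speciation_vs_pzn(m, seq(6, 12, by = 1))
  d <- as.data.frame(pr)
  expect_named(d, c("axis", "species", "fraction", "free_zn_M"))
  expect_equal(nrow(d), 7 * 3)
  expect_equal(sort(unique(d$species)), c("Zn0", "Zn1", "Zn2"))
})
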