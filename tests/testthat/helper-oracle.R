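# Independent equilibrium oracle: the mass-balance residual is written
# out from the component definitions and the root is located by a dense
# log-grid sign scan with repeated zooming -- no shared code path with
# the package's bisection/Newton solver.

oracle_residual <- function(system, lz) {
  vapply(lz, function(l) {
    z <- 10^l
    b <- 0
    if (!is.null(system$protein) && system$protein_total > 0) {
      lb <- cumsum(system$protein$pkd_steps)
      i <- seq_along(lb)
      lw <- c(0, lb + i * l)
      w <- 10^(lw - max(lw))
      b <- b + system$protein_total * sum((0:length(lb)) * w) / sum(w)
    }
    for (ch in system$chelators)
      b <- b + ch$total * z / (z + 10^(-ch$component$pkd))
    if (!is.null(system$probe_1to1) && system$probe_1to1$total > 0)
      b <- b + system$probe_1to1$total * z /
        (z + 10^(-system$probe_1to1$component$pkd))
    if (!is.null(system$probe_2to1) && system$probe_2to1$total > 0) {
      kd12 <- system$probe_2to1$component$kd12
      ptot <- system$probe_2to1$total
      pf <- 2 * ptot / (1 + sqrt(1 + 8 * z * ptot / kd12))
      b <- b + z * pf^2 / kd12
    }
    z + b - system$zn_total
  }, numeric(1))
}

oracle_free_zinc <- function(system, lo = -20, hi = -1, rounds = 4L,
                             n_grid = 400L) {
  for (r in seq_len(rounds)) {
    lz <- seq(lo, hi, length.out = n_grid)
    f <- oracle_residual(system, lz)
    ix <- which(f[-1] >= 0 & f[-length(f)] < 0)[1]
    if (is.na(ix)) stop("oracle: no sign change in bracket")
    lo <- lz[ix]; hi <- lz[ix + 1L]
  }
  (lo + hi) / 2
}

# Randomized test systems: 1-5 protein sites with pkds in [5, 16],
# totals in [1e-7, 1e-3] M, optional chelator and probes.
random_system <- function() {
  n <- sample(1:5, 1)
  model <- binding_model("rand", sort(runif(n, 5, 16), decreasing = TRUE))
  p_tot <- 10^runif(1, -7, -3)
  chel <- if (runif(1) < 0.5)
    list(list(chelator("C", runif(1, 5, 16)), 10^runif(1, -7, -3)))
  p11 <- if (runif(1) < 0.5) list(probe_1to1(), 10^runif(1, -7, -3))
  p21 <- if (runif(1) < 0.5) list(probe_2to1(), 10^runif(1, -7, -3))
  capacity <- n * p_tot +
    sum(vapply(chel, function(x) x[[2]], numeric(1))) +
    (if (is.null(p11)) 0 else p11[[2]]) +
    (if (is.null(p21)) 0 else p21[[2]] / 2)
  zn <- runif(1, 0.05, 1.3) * capacity
  equilibrium_system(protein = model, protein_total = p_tot,
                     chelators = chel, probe_1to1 = p11, probe_2to1 = p21,
                     zn_total = min(zn, 0.05))
}

fixture_registry <- function() {
  if (is.null(.helper_env$registry))
    .helper_env$registry <- make_fixture_models()
  .helper_env$registry
}
.helper_env <- new.env()

# Range-scaled Gaussian noise for ad-hoc vectors in tests.
apply_noise_for_test <- function(y, sigma, seed) {
  set.seed(seed)
  y + stats::rnorm(length(y), sd = sigma * diff(range(y)))
}
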