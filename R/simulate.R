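#' Gaussian noise specification for simulated signals
#'
#' Noise is applied in signal space, with `sigma` expressed as a
#' fraction of the simulated trace's dynamic range — the way instrument
#' noise presents. The same seed always yields the same dataset.
#'
#' @param sigma Noise amplitude as a fraction of dynamic range (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  stopifnot(is.numeric(sigma), sigma >= 0, is.numeric(seed))
  structure(list(kind = "gaussian", sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# Add range-scaled Gaussian noise to a signal vector, deterministically
# under the spec's seed; restores the caller's RNG state.
apply_noise <- function(signal, noise) {
  if (is.null(noise) || noise$sigma == 0) return(signal)
  rng <- diff(range(signal))
  if (rng == 0) rng <- max(abs(signal), 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  signal + stats::rnorm(length(signal), sd = noise$sigma * rng)
}

#' Simulate a chromogenic-probe competition transfer
#'
#' Forward model of a 2:1 probe competition: the fully loaded protein
#' (`zn_total = n_sites * protein_total`) is equilibrated with the probe
#' and the transferred Zn(II) mol equivalents are read off the bis
#' complex concentration.
#'
#' @param model A [binding_model()].
#' @param protein_total,par_total Totals, M.
#' @param probe A [probe_2to1()].
#' @param noise Optional [noise_spec()] applied to the transfer value.
#' @return A [transfer_observation()].
#' @export
simulate_par_transfer <- function(model, protein_total, par_total,
                                  probe = probe_2to1(), noise = NULL) {
  stopifnot(protein_total > 0, par_total >= 0)
  if (par_total == 0) {
    t_eq <- 0
  } else {
    sys <- equilibrium_system(
      protein = model, protein_total = protein_total,
      probe_2to1 = list(probe, par_total),
      zn_total = model$n_sites * protein_total)
    sol <- solve_free_zinc(sys)
    znp2 <- sol$species[[paste0("Zn(", probe$name, ")2")]]
    t_eq <- znp2 / protein_total
  }
  if (!is.null(noise) && noise$sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
    t_eq <- max(t_eq + stats::rnorm(1, sd = noise$sigma * model$n_sites), 0)
  }
  transfer_observation(min(t_eq, model$n_sites), protein_total, par_total,
                       model$n_sites)
}

#' Simulate a fluorescent-probe transfer isotherm
#'
#' Forward model of Zn(II) transfer from the fully loaded protein to
#' increasing amounts of a 1:1 fluorescent probe: one equilibrium solve
#' per probe level, reporting transferred mol equivalents and the
#' resulting pZn.
#'
#' @param model A [binding_model()].
#' @param protein_total Total protein, M.
#' @param probe_grid Increasing probe totals, M (> 0).
#' @param probe A [probe_1to1()].
#' @param noise Optional [noise_spec()] applied to the transfer values.
#' @return data.frame with columns `probe_total`, `transferred_eq`,
#'   `pzn`.
#' @export
simulate_znaf_transfer_isotherm <- function(model, protein_total, probe_grid,
                                            probe = probe_1to1(),
                                            noise = NULL) {
  stopifnot(protein_total > 0, all(probe_grid > 0))
  if (is.unsorted(probe_grid, strictly = TRUE))
    stop("'probe_grid' must be strictly increasing", call. = FALSE)
  t_eq <- numeric(length(probe_grid))
  pzn <- numeric(length(probe_grid))
  for (k in seq_along(probe_grid)) {
    sys <- equilibrium_system(
      protein = model, protein_total = protein_total,
      probe_1to1 = list(probe, probe_grid[k]),
      zn_total = model$n_sites * protein_total)
    sol <- solve_free_zinc(sys)
    t_eq[k] <- sol$species[[paste0("Zn-", probe$name)]] / protein_total
    pzn[k] <- sol$pzn
  }
  data.frame(probe_total = probe_grid,
             transferred_eq = apply_noise(t_eq, noise),
             pzn = pzn)
}

#' Simulate an apo-protein titration in the presence of a 1:1 probe
#'
#' Forward model of titrating apo-protein plus probe with Zn(II): at
#' each Zn(II)/protein ratio the equilibrium is solved and the probe
#' fluorescence (arbitrary units, `f_min = 0`, `f_max = 1` before
#' noise) and pZn are recorded.
#'
#' @param model A [binding_model()].
#' @param protein_total,probe_total Totals, M.
#' @param zn_grid Zn(II)/apo-protein molar ratios (>= 0, increasing).
#' @param probe A [probe_1to1()].
#' @param noise Optional [noise_spec()] applied to the fluorescence.
#' @return data.frame with columns `ratio`, `fluorescence`, `pzn`
#'   (pzn is `NA` at ratio 0).
#' @export
simulate_apo_titration <- function(model, protein_total, probe_total,
                                   zn_grid, probe = probe_1to1(),
                                   noise = NULL) {
  stopifnot(protein_total > 0, probe_total > 0, all(zn_grid >= 0))
  if (is.unsorted(zn_grid, strictly = TRUE))
    stop("'zn_grid' must be strictly increasing", call. = FALSE)
  cal <- fluorescence_calibration(0, 1, probe)
  fl <- numeric(length(zn_grid)); pzn <- numeric(length(zn_grid))
  for (k in seq_along(zn_grid)) {
    sys <- equilibrium_system(
      protein = model, protein_total = protein_total,
      probe_1to1 = list(probe, probe_total),
      zn_total = zn_grid[k] * protein_total)
    sol <- solve_free_zinc(sys)
    if (sol$all_apo) {
      fl[k] <- 0; pzn[k] <- NA_real_
    } else {
      fl[k] <- fluorescence_from_free_zinc(sol$free_zn, cal)
      pzn[k] <- sol$pzn
    }
  }
  data.frame(ratio = zn_grid, fluorescence = apply_noise(fl, noise),
             pzn = pzn)
}

#' Simulate a pH titration with a Hill transition
#'
#' @param pka_prime Apparent average thiol pKa'.
#' @param n Hill coefficient.
#' @param plateaus `c(a_lo, a_hi)` absorbance plateaus.
#' @param grid pH grid (monotone).
#' @param noise Optional [noise_spec()].
#' @return data.frame with columns `ph`, `absorbance`.
#' @export
simulate_ph_titration <- function(pka_prime, n, plateaus, grid,
                                  noise = NULL) {
  stopifnot(length(plateaus) == 2L, length(grid) >= 2L)
  if (is.unsorted(grid, strictly = TRUE) &&
      is.unsorted(rev(grid), strictly = TRUE))
    stop("'grid' must be strictly monotone", call. = FALSE)
  a <- plateaus[1L] + (plateaus[2L] - plateaus[1L]) /
    (1 + 10^(n * (pka_prime - grid)))
  data.frame(ph = grid, absorbance = apply_noise(a, noise))
}

#' Simulate a metal-buffer CD competition series
#'
#' Forward model of a complexone competition read out by CD: for each
#' buffer composition (chelator, fractional saturation) the full
#' equilibrium `{chelator + protein, zn_total = f * L_tot}` is solved
#' and the ellipticity is taken proportional to the loading of the
#' protein's CD-visible sites (`cd_model`), scaled between the apo and
#' holo plateaus. `pzn_initial` is the buffer's nominal free Zn(II)
#' before protein addition ([buffer_free_zinc()]).
#'
#' @param cd_model A [binding_model()] of the CD-visible sites (for a
#'   zinc-finger-type protein, the tight sites).
#' @param chelators Named list of [chelator()] objects.
#' @param fractions Fractional saturations in (0, 1) applied to every
#'   chelator.
#' @param protein_total,chelator_total Totals, M.
#' @param plateaus `c(e_apo, e_holo)` ellipticity plateaus (mdeg).
#' @param noise Optional [noise_spec()].
#' @return data.frame with columns `pzn_initial`, `ellipticity`,
#'   `chelator`, `chelator_total`, `zn_fraction`.
#' @export
simulate_buffer_cd <- function(cd_model, chelators, fractions,
                               protein_total, chelator_total = 5e-4,
                               plateaus = c(0, -30), noise = NULL) {
  stopifnot(inherits(cd_model, "stepped_binding_model"),
            all(fractions > 0), all(fractions < 1), protein_total > 0)
  rows <- expand.grid(chelator = names(chelators), f = fractions,
                      stringsAsFactors = FALSE)
  ell <- numeric(nrow(rows)); pzn0 <- numeric(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    ch <- chelators[[rows$chelator[k]]]
    f <- rows$f[k]
    pzn0[k] <- -log10(buffer_free_zinc(ch, f))
    sys <- equilibrium_system(
      protein = cd_model, protein_total = protein_total,
      chelators = list(list(ch, chelator_total)),
      zn_total = f * chelator_total)
    sol <- solve_free_zinc(sys)
    occ <- mean_occupancy(cd_model, sol$free_zn) / cd_model$n_sites
    ell[k] <- plateaus[1L] + (plateaus[2L] - plateaus[1L]) * occ
  }
  data.frame(pzn_initial = pzn0, ellipticity = apply_noise(ell, noise),
             chelator = rows$chelator, chelator_total = chelator_total,
             zn_fraction = rows$f)
}

#' Simulate an exponential kinetic trace
#'
#' `A(t) = offset + amplitude (1 - exp(-k t))` with optional Gaussian
#' noise.
#'
#' @param k_obsd Rate constant, s^-1 (> 0).
#' @param amplitude,offset Signal parameters.
#' @param t_grid Time grid, s (strictly increasing, >= 5 points).
#' @param noise Optional [noise_spec()].
#' @return A [kinetic_trace()].
#' @export
simulate_kinetic_trace <- function(k_obsd, amplitude = 1, offset = 0,
                                   t_grid = seq(0, 600, by = 10),
                                   noise = NULL) {
  stopifnot(k_obsd > 0)
  a <- offset + amplitude * (1 - exp(-k_obsd * t_grid))
  kinetic_trace(t_grid, apply_noise(a, noise),
                metadata = list(k_true = k_obsd))
}
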