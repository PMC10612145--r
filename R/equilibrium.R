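#' Multi-component Zn(II) equilibrium system
#'
#' Bundles the totals of Zn(II) and any mixture of a stepwise-binding
#' protein, 1:1 chelators, a 2:1 chromogenic probe, and a 1:1 fluorescent
#' probe, to be solved for free Zn(II) at fixed pH by
#' [solve_free_zinc()].
#'
#' @param protein Optional [binding_model()].
#' @param protein_total Total protein, M (required with `protein`).
#' @param chelators Optional list of `list(chelator, total)` pairs, each
#'   `chelator` from [chelator()].
#' @param probe_2to1 Optional `list(probe, total)` with a [probe_2to1()].
#' @param probe_1to1 Optional `list(probe, total)` with a [probe_1to1()].
#' @param zn_total Total Zn(II), M (>= 0).
#' @return An object of class `equilibrium_system`.
#' @export
equilibrium_system <- function(protein = NULL, protein_total = 0,
                               chelators = NULL, probe_2to1 = NULL,
                               probe_1to1 = NULL, zn_total = 0) {
  if (!is.null(protein)) {
    stopifnot(inherits(protein, "stepped_binding_model"),
              is.numeric(protein_total), protein_total >= 0)
  } else {
    protein_total <- 0
  }
  check_pair <- function(p, cls, what) {
    if (is.null(p)) return(NULL)
    if (!is.list(p) || length(p) < 2L || !inherits(p[[1L]], cls) ||
        !is.numeric(p[[2L]]) || p[[2L]] < 0)
      stop(sprintf("'%s' must be list(<%s>, total >= 0)", what, cls),
           call. = FALSE)
    list(component = p[[1L]], total = as.numeric(p[[2L]]))
  }
  chel <- NULL
  if (!is.null(chelators)) {
    if (inherits(chelators, "chelator_1to1"))
      stop("'chelators' must be a list of list(chelator, total) pairs",
           call. = FALSE)
    chel <- lapply(chelators, check_pair, cls = "chelator_1to1",
                   what = "chelators[[i]]")
  }
  if (!is.numeric(zn_total) || zn_total < 0)
    stop("'zn_total' must be >= 0", call. = FALSE)
  structure(
    list(protein = protein, protein_total = protein_total,
         chelators = chel,
         probe_2to1 = check_pair(probe_2to1, "probe_2to1", "probe_2to1"),
         probe_1to1 = check_pair(probe_1to1, "probe_1to1", "probe_1to1"),
         zn_total = zn_total),
    class = "equilibrium_system"
  )
}

# Free ligand of the 2:1 probe at free Zn z, from its own mass balance
# P_tot = P_free + 2 z P_free^2 / Kd12 (stable root of the quadratic).
par_free_ligand <- function(z, p_total, kd12) {
  if (p_total == 0) return(0)
  a <- 2 * z / kd12
  2 * p_total / (1 + sqrt(1 + 4 * a * p_total))
}

# Scalar fast path for the protein binding curve (hot loop of the
# bisection solver); matches mean_occupancy.
occupancy_scalar <- function(model, z) {
  lb <- cumsum(model$pkd_steps)
  i <- seq_along(lb)
  lw <- lb + i * log10(z)
  m <- max(0, lw)
  sw <- 10^(lw - m)
  sum(i * sw) / (10^(-m) + sum(sw))
}

# Total Zn bound by every component at free Zn z.
bound_zinc <- function(system, z) {
  bound <- 0
  if (!is.null(system$protein) && system$protein_total > 0)
    bound <- bound + system$protein_total * occupancy_scalar(system$protein, z)
  for (ch in system$chelators) {
    kd <- 10^(-ch$component$pkd)
    bound <- bound + ch$total * z / (z + kd)
  }
  if (!is.null(system$probe_1to1) && system$probe_1to1$total > 0) {
    kd <- 10^(-system$probe_1to1$component$pkd)
    bound <- bound + system$probe_1to1$total * z / (z + kd)
  }
  if (!is.null(system$probe_2to1) && system$probe_2to1$total > 0) {
    kd12 <- system$probe_2to1$component$kd12
    pf <- par_free_ligand(z, system$probe_2to1$total, kd12)
    bound <- bound + z * pf^2 / kd12
  }
  bound
}

#' Solve a Zn(II) mass-balance equilibrium for free Zn(II)
#'
#' Finds the free Zn(II) concentration `z` solving the scalar mass
#' balance `zn_total = z + sum(bound_c(z))` over all components, where
#' the protein contributes `protein_total * mean_occupancy(z)`, each 1:1
#' ligand contributes `L_tot * z / (z + Kd)`, and the 2:1 probe's ligand
#' mass balance (`P_tot = P_free + 2 [ZnP2]`,
#' `[ZnP2] = z P_free^2 / Kd12`) is solved jointly in closed form. The
#' root is bracketed by monotone bisection on `log10 z` over
#' `[-20, -1]` (200 iterations maximum), then polished with up to 5
#' damped Newton steps.
#'
#' @param system An [equilibrium_system()].
#' @param tol Relative mass-balance tolerance (default 1e-8).
#' @return List with elements `free_zn` (M), `pzn`, `species` (named
#'   concentrations in M of every species: `Zn0..Znx` protein forms,
#'   `Zn-<chelator>` complexes, free and Zn-bound probe), `residual`
#'   (relative mass-balance error), and `all_apo` (TRUE for the
#'   `zn_total = 0` sentinel, where `free_zn = 0` and `pzn = NA`).
#' @export
solve_free_zinc <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "equilibrium_system"))
  if (system$zn_total == 0)
    return(list(free_zn = 0, pzn = NA_real_,
                species = species_table(system, 0, all_apo = TRUE),
                residual = 0, all_apo = TRUE))
  resid <- function(lz) {
    z <- 10^lz
    z + bound_zinc(system, z) - system$zn_total
  }
  lo <- -20; hi <- -1
  flo <- resid(lo); fhi <- resid(hi)
  if (flo > 0) {
    # essentially all Zn free even at the bracket floor: zn_total tiny
    if (system$zn_total <= 10^lo)
      return(list(free_zn = system$zn_total, pzn = -log10(system$zn_total),
                  species = species_table(system, system$zn_total),
                  residual = 0, all_apo = FALSE))
    stop("mass-balance residual positive over the whole bracket [-20, -1]",
         call. = FALSE)
  }
  if (fhi < 0)
    stop(sprintf(paste0("zn_total (%.3g M) exceeds free + bound capacity at ",
                        "the bracket ceiling 0.1 M"), system$zn_total),
         call. = FALSE)
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (fm < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  lz <- (lo + hi) / 2
  # Newton polish on log10 z with numeric derivative, kept inside bracket
  for (it in seq_len(5L)) {
    f0 <- resid(lz)
    h <- 1e-7
    d <- (resid(lz + h) - resid(lz - h)) / (2 * h)
    if (!is.finite(d) || d <= 0) break
    step <- f0 / d
    cand <- lz - step
    if (cand <= lo || cand >= hi) break
    lz <- cand
  }
  z <- 10^lz
  residual <- abs(z + bound_zinc(system, z) - system$zn_total) /
    max(system$zn_total, 1e-30)
  if (residual > tol)
    stop(sprintf("equilibrium solver did not reach tolerance (residual %.3g)",
                 residual), call. = FALSE)
  list(free_zn = z, pzn = -log10(z),
       species = species_table(system, z),
       residual = residual, all_apo = FALSE)
}

# Named species concentrations at free Zn z.
species_table <- function(system, z, all_apo = FALSE) {
  out <- c(`Zn_free` = z)
  if (!is.null(system$protein) && system$protein_total > 0) {
    n <- system$protein$n_sites
    frac <- if (all_apo || z <= 0) c(1, rep(0, n))
            else species_fractions_at_free_zn(system$protein, z)
    conc <- system$protein_total * frac
    names(conc) <- paste0("Zn", 0:n, "_", system$protein$name)
    out <- c(out, conc)
  }
  for (ch in system$chelators) {
    kd <- 10^(-ch$component$pkd)
    znl <- if (z > 0) ch$total * z / (z + kd) else 0
    v <- c(znl, ch$total - znl)
    names(v) <- paste0(c("Zn-", "free_"), ch$component$name)
    out <- c(out, v)
  }
  if (!is.null(system$probe_1to1) && system$probe_1to1$total > 0) {
    kd <- 10^(-system$probe_1to1$component$pkd)
    znp <- if (z > 0) system$probe_1to1$total * z / (z + kd) else 0
    v <- c(znp, system$probe_1to1$total - znp)
    names(v) <- paste0(c("Zn-", "free_"), system$probe_1to1$component$name)
    out <- c(out, v)
  }
  if (!is.null(system$probe_2to1) && system$probe_2to1$total > 0) {
    kd12 <- system$probe_2to1$component$kd12
    pf <- if (z > 0) par_free_ligand(z, system$probe_2to1$total, kd12)
          else system$probe_2to1$total
    znp2 <- if (z > 0) z * pf^2 / kd12 else 0
    v <- c(znp2, pf)
    names(v) <- paste0(c("Zn(", "free_"), system$probe_2to1$component$name,
                       c(")2", ""))
    out <- c(out, v)
  }
  out
}
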