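#' Molar fractions of Zn_i protein species at a given free Zn(II)
#'
#' Closed-form Adair speciation: the `Zn_i` species weight is
#' `beta_i * z^i` (with `beta_0 = 1`), normalized to unit sum. Weights
#' are formed in log10 space with max-subtraction so that models with
#' `log10 beta` up to ~90 evaluate without overflow.
#'
#' @param model A [binding_model()].
#' @param free_zn Free Zn(II) concentration, M (> 0). May be a vector.
#' @return If `free_zn` is scalar, a numeric vector of `n_sites + 1`
#'   molar fractions (`Zn_0` first); otherwise a matrix with one row per
#'   `free_zn` value.
#' @export
species_fractions_at_free_zn <- function(model, free_zn) {
  stopifnot(inherits(model, "stepped_binding_model"))
  if (any(!is.finite(free_zn)) || any(free_zn <= 0))
    stop("'free_zn' must be positive and finite", call. = FALSE)
  log_betas <- c(0, cumulative_log_betas(model))
  i <- 0:model$n_sites
  # rows: free_zn values; cols: species 0..n
  logw <- outer(log10(free_zn), i) + rep(log_betas, each = length(free_zn))
  logw <- logw - apply(logw, 1L, max)
  w <- 10^logw
  frac <- w / rowSums(w)
  if (length(free_zn) == 1L) drop(frac) else frac
}

#' Mean Zn(II) occupancy of a protein at a given free Zn(II)
#'
#' `sum(i * fraction_i)`, the Adair binding curve; strictly increasing in
#' `free_zn`, ranging over (0, n_sites).
#'
#' @inheritParams species_fractions_at_free_zn
#' @return Numeric, same length as `free_zn`.
#' @export
mean_occupancy <- function(model, free_zn) {
  frac <- species_fractions_at_free_zn(model, free_zn)
  i <- 0:model$n_sites
  if (is.matrix(frac)) drop(frac %*% i) else sum(frac * i)
}

new_speciation_profile <- function(axis_kind, axis, fractions, free_zn,
                                   model) {
  colnames(fractions) <- paste0("Zn", 0:(ncol(fractions) - 1L))
  structure(
    list(axis_kind = axis_kind, axis = axis, fractions = fractions,
         free_zn = free_zn, model_name = model$name,
         n_sites = model$n_sites),
    class = "speciation_profile"
  )
}

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("<speciation_profile> %s over %d %s points (species Zn0..Zn%d)\n",
              x$model_name, length(x$axis), x$axis_kind, x$n_sites))
  invisible(x)
}

#' Tidy data.frame representation of a speciation profile
#'
#' @param x A `speciation_profile`.
#' @param row.names,optional,... Ignored; present for method consistency.
#' @return data.frame with columns `axis`, `species`, `fraction`,
#'   `free_zn_M`.
#' @export
as.data.frame.speciation_profile <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  species <- colnames(x$fractions)
  data.frame(
    axis = rep(x$axis, times = length(species)),
    species = rep(species, each = length(x$axis)),
    fraction = as.vector(x$fractions),
    free_zn_M = rep(x$free_zn, times = length(species))
  )
}

#' Speciation profile over a pZn grid
#'
#' Free Zn(II) is the independent variable, so each grid point is a
#' closed-form evaluation (no equilibrium solve).
#'
#' @param model A [binding_model()].
#' @param pzn_grid Strictly monotone numeric grid of pZn values
#'   (`-log10` free Zn in M).
#' @return A `speciation_profile` with `axis_kind = "pzn"`.
#' @export
speciation_vs_pzn <- function(model, pzn_grid) {
  stopifnot(inherits(model, "stepped_binding_model"))
  if (length(pzn_grid) == 0L) stop("empty pZn grid", call. = FALSE)
  if (length(pzn_grid) > 1L) {
    d <- diff(pzn_grid)
    if (!(all(d > 0) || all(d < 0)))
      stop("'pzn_grid' must be strictly monotone", call. = FALSE)
  }
  z <- 10^(-pzn_grid)
  frac <- species_fractions_at_free_zn(model, z)
  if (!is.matrix(frac)) frac <- matrix(frac, nrow = 1L)
  new_speciation_profile("pzn", pzn_grid, frac, z, model)
}

#' Speciation profile over a Zn(II)/apo-protein ratio grid
#'
#' For each ratio `r` the full mass balance with
#' `zn_total = r * protein_total` is solved (optionally with extra
#' competing components present), and protein species fractions plus free
#' Zn(II) are recorded.
#'
#' @param model A [binding_model()].
#' @param protein_total Total protein, M (> 0).
#' @param ratio_grid Non-negative Zn(II)/protein molar ratios.
#' @param extra_components Optional list with any of `chelators` (list of
#'   `list(chelator, total)`), `probe_2to1` (`list(probe, total)`),
#'   `probe_1to1` (`list(probe, total)`), passed to
#'   [equilibrium_system()].
#' @return A `speciation_profile` with `axis_kind = "ratio"`.
#' @export
speciation_vs_ratio <- function(model, protein_total, ratio_grid,
                                extra_components = NULL) {
  stopifnot(inherits(model, "stepped_binding_model"),
            is.numeric(protein_total), protein_total > 0)
  if (length(ratio_grid) == 0L) stop("empty ratio grid", call. = FALSE)
  if (any(ratio_grid < 0)) stop("ratios must be >= 0", call. = FALSE)
  n <- model$n_sites
  frac <- matrix(NA_real_, nrow = length(ratio_grid), ncol = n + 1L)
  free_zn <- numeric(length(ratio_grid))
  for (k in seq_along(ratio_grid)) {
    sys <- equilibrium_system(
      protein = model, protein_total = protein_total,
      chelators = extra_components$chelators,
      probe_2to1 = extra_components$probe_2to1,
      probe_1to1 = extra_components$probe_1to1,
      zn_total = ratio_grid[k] * protein_total
    )
    sol <- tryCatch(solve_free_zinc(sys), error = function(e)
      stop(sprintf("equilibrium solve failed at ratio grid point %d (r = %g): %s",
                   k, ratio_grid[k], conditionMessage(e)), call. = FALSE))
    free_zn[k] <- sol$free_zn
    if (sol$all_apo) {
      frac[k, ] <- c(1, rep(0, n))
    } else {
      frac[k, ] <- species_fractions_at_free_zn(model, sol$free_zn)
    }
  }
  new_speciation_profile("ratio", ratio_grid, frac, free_zn, model)
}

#' pZn at which a partially metalated species is most abundant
#'
#' The molar fraction of species `i` is maximal in pZn exactly where the
#' mean occupancy equals `i` (the stationarity condition of the Adair
#' fractions), so the peak is located by bisection on
#' `mean_occupancy(z) = i`. Terminal species (`i = 0`, `i = n_sites`)
#' have no interior maximum and return `Inf` / `-Inf` with
#' `interior = FALSE`.
#'
#' @param model A [binding_model()].
#' @param species_index Integer in `0..n_sites`.
#' @param pzn_range Search interval on the pZn axis.
#' @param tol Bisection tolerance on pZn (default gives >= 3 decimals).
#' @return List with `pzn` (peak position), `interior` (logical flag).
#' @export
peak_pzn <- function(model, species_index, pzn_range = c(1, 20),
                     tol = 1e-4) {
  stopifnot(inherits(model, "stepped_binding_model"))
  n <- model$n_sites
  if (species_index < 0 || species_index > n || species_index != round(species_index))
    stop("'species_index' must be an integer in 0..n_sites", call. = FALSE)
  if (species_index == 0L)
    return(list(pzn = Inf, interior = FALSE))
  if (species_index == n)
    return(list(pzn = -Inf, interior = FALSE))
  f <- function(pzn) mean_occupancy(model, 10^(-pzn)) - species_index
  lo <- min(pzn_range); hi <- max(pzn_range)
  # occupancy decreases with pzn: f(lo) > 0 > f(hi)
  if (f(lo) < 0 || f(hi) > 0)
    stop("peak lies outside 'pzn_range'", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  list(pzn = (lo + hi) / 2, interior = TRUE)
}

#' Zinc buffering window on the pZn scale
#'
#' Interval of pZn over which the protein's mean occupancy runs from
#' `coverage * n_sites` (Zn-rich end, low pZn) down to
#' `(1 - coverage) * n_sites` (Zn-poor end, high pZn): the span across
#' which the protein can absorb or release the bulk of its Zn(II) load.
#'
#' @param model A [binding_model()].
#' @param coverage Fraction in (0, 1); default 0.9 (a 10-90% window).
#' @param pzn_range Search interval.
#' @return Numeric `c(pzn_low, pzn_high)`.
#' @export
buffering_window <- function(model, coverage = 0.9, pzn_range = c(0, 25)) {
  stopifnot(inherits(model, "stepped_binding_model"),
            coverage > 0, coverage < 1)
  n <- model$n_sites
  solve_occ <- function(target) {
    f <- function(pzn) mean_occupancy(model, 10^(-pzn)) - target
    lo <- min(pzn_range); hi <- max(pzn_range)
    if (f(lo) < 0 || f(hi) > 0)
      stop("buffering window outside 'pzn_range'", call. = FALSE)
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(pzn_low = solve_occ(coverage * n), pzn_high = solve_occ((1 - coverage) * n))
}
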