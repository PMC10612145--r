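#' Fluorescence calibration for a 1:1 Zn(II) probe
#'
#' Per-sample calibration of a ratiometric free-Zn(II) readout:
#' `f_min` is the fully Zn-free probe signal (chelator-saturated),
#' `f_max` the Zn-saturated signal. Conversions are ratio-based, so the
#' fluorescence units are arbitrary.
#'
#' @param f_min,f_max Probe fluorescence at zero and full Zn(II)
#'   saturation (`f_max > f_min`).
#' @param probe A [probe_1to1()].
#' @return An object of class `fluorescence_calibration`.
#' @export
fluorescence_calibration <- function(f_min, f_max, probe = probe_1to1()) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), f_max > f_min,
            inherits(probe, "probe_1to1"))
  structure(list(f_min = f_min, f_max = f_max, probe = probe),
            class = "fluorescence_calibration")
}

#' Free Zn(II) from probe fluorescence
#'
#' `free Zn = Kd * (F - F_min) / (F_max - F)`: the probe's fractional
#' saturation converted through its 1:1 dissociation constant.
#' `F >= F_max` (probe saturated, free Zn unbounded) is an error;
#' `F < F_min` is clamped to 0 with a warning.
#'
#' @param f Measured fluorescence (same arbitrary units as the
#'   calibration). May be a vector.
#' @param cal A [fluorescence_calibration()].
#' @return Free Zn(II), M.
#' @export
free_zinc_from_fluorescence <- function(f, cal) {
  stopifnot(inherits(cal, "fluorescence_calibration"))
  if (any(f >= cal$f_max))
    stop("fluorescence at or above f_max: probe saturated, free Zn(II) undefined",
         call. = FALSE)
  below <- f < cal$f_min
  if (any(below)) {
    warning("fluorescence below f_min clamped to free Zn(II) = 0")
    f[below] <- cal$f_min
  }
  kd <- 10^(-cal$probe$pkd)
  kd * (f - cal$f_min) / (cal$f_max - f)
}

#' Probe fluorescence from free Zn(II) (inverse calibration)
#'
#' Exact inverse of [free_zinc_from_fluorescence()]:
#' `F = F_min + (F_max - F_min) * z / (z + Kd)`.
#'
#' @param free_zn Free Zn(II), M (>= 0). May be a vector.
#' @param cal A [fluorescence_calibration()].
#' @return Fluorescence in calibration units.
#' @export
fluorescence_from_free_zinc <- function(free_zn, cal) {
  stopifnot(inherits(cal, "fluorescence_calibration"))
  if (any(free_zn < 0)) stop("'free_zn' must be >= 0", call. = FALSE)
  kd <- 10^(-cal$probe$pkd)
  cal$f_min + (cal$f_max - cal$f_min) * free_zn / (free_zn + kd)
}

#' Zn(II)-bis(ligand) complex concentration from absorbance
#'
#' Beer-Lambert: `[ZnL2] = A / (epsilon * path)` using the probe's
#' complex absorptivity.
#'
#' @param a_492 Baseline-corrected absorbance (>= 0). May be a vector.
#' @param probe A [probe_2to1()].
#' @return Complex concentration, M.
#' @export
znpar2_from_absorbance <- function(a_492, probe = probe_2to1()) {
  stopifnot(inherits(probe, "probe_2to1"))
  if (any(a_492 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  a_492 / (probe$epsilon_492 * probe$path_length)
}

#' Free Zn(II) from the 2:1 probe equilibrium
#'
#' With the bis-ligand complex at `[ZnL2]` and total ligand `L_tot`,
#' free ligand is `L_tot - 2 [ZnL2]` and
#' `free Zn = Kd12 * [ZnL2] / (L_tot - 2 [ZnL2])^2`.
#'
#' @param znpar2 Complex concentration, M. May be a vector.
#' @param par_total Total ligand, M.
#' @param probe A [probe_2to1()].
#' @return Free Zn(II), M.
#' @export
free_zinc_from_par <- function(znpar2, par_total, probe = probe_2to1()) {
  stopifnot(inherits(probe, "probe_2to1"), par_total > 0)
  if (any(znpar2 < 0)) stop("'znpar2' must be >= 0", call. = FALSE)
  if (any(2 * znpar2 >= par_total))
    stop("probe depleted: 2*[ZnL2] >= total ligand", call. = FALSE)
  probe$kd12 * znpar2 / (par_total - 2 * znpar2)^2
}

#' Free Zn(II) fixed by a partially saturated 1:1 metal buffer
#'
#' A chelator loaded to fractional Zn(II) saturation `f` buffers free
#' Zn(II) at `Kd * f / (1 - f)` (ligand-excess form of the 1:1
#' equilibrium).
#'
#' @param chelator A [chelator()].
#' @param zn_fraction Fractional saturation in (0, 1). May be a vector.
#' @return Free Zn(II), M.
#' @export
buffer_free_zinc <- function(chelator, zn_fraction) {
  stopifnot(inherits(chelator, "chelator_1to1"))
  if (any(zn_fraction <= 0) || any(zn_fraction >= 1))
    stop("'zn_fraction' must lie strictly within (0, 1)", call. = FALSE)
  10^(-chelator$pkd) * zn_fraction / (1 - zn_fraction)
}

#' Transfer observation from a probe-competition experiment
#'
#' One equilibrium observation of Zn(II) mol equivalents transferred from
#' a loaded protein to a competitor in excess.
#'
#' @param transferred_eq Mol Zn(II) transferred per mol protein
#'   (`0 <= t <= n_sites`).
#' @param protein_total Total protein, M (> 0).
#' @param competitor_total Total competitor ligand, M (> 0).
#' @param n_sites Maximum Zn(II) load of the protein.
#' @return An object of class `transfer_observation`.
#' @export
transfer_observation <- function(transferred_eq, protein_total,
                                 competitor_total, n_sites) {
  stopifnot(is.numeric(transferred_eq), transferred_eq >= 0,
            transferred_eq <= n_sites, protein_total > 0,
            competitor_total >= 0, n_sites >= 1,
            n_sites == round(n_sites))
  structure(list(transferred_eq = transferred_eq,
                 protein_total = protein_total,
                 competitor_total = competitor_total,
                 n_sites = as.integer(n_sites)),
            class = "transfer_observation")
}
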