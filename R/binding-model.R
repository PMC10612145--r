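#' Stepwise Zn(II) binding model
#'
#' Represents a multi-site metalloprotein by its macroscopic stepwise
#' apparent dissociation constants at fixed pH, stored as `-log10` molar
#' values (`pkd`). Step `i` describes the association of the i-th Zn(II)
#' onto the `Zn_(i-1)` protein, ordered tightest first, so `pkd_steps`
#' must be non-increasing. Cumulative association constants
#' `log10 beta_i = sum(pkd_steps[1:i])` are kept in log space throughout:
#' for a 9-site protein `beta_9` can reach ~1e90 and is never formed as a
#' double.
#'
#' Constants are macroscopic conditional constants as tabulated for a
#' stated pH; no proton competition or statistical factors are added.
#'
#' @param name Text label for the protein.
#' @param pkd_steps Numeric vector of stepwise `-log10 Kd` values (molar),
#'   tightest first (non-increasing). Its length defines `n_sites`.
#' @return An object of class `stepped_binding_model` with fields `name`,
#'   `n_sites`, `pkd_steps`.
#' @examples
#' xlmt <- binding_model("XlMT", c(11.2, 11.2, 11.2, 11.2, 10.1, 9.37, 7.74))
#' cumulative_log_betas(xlmt)
#' @export
binding_model <- function(name, pkd_steps) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pkd_steps <- as.numeric(pkd_steps)
  if (length(pkd_steps) < 1L)
    stop("'pkd_steps' must contain at least one step", call. = FALSE)
  if (any(!is.finite(pkd_steps)) || any(pkd_steps <= 0))
    stop("all 'pkd_steps' must be finite and > 0", call. = FALSE)
  if (is.unsorted(rev(pkd_steps), strictly = FALSE))
    stop("'pkd_steps' must be non-increasing (tightest site first)",
         call. = FALSE)
  structure(
    list(name = name, n_sites = length(pkd_steps), pkd_steps = pkd_steps),
    class = "stepped_binding_model"
  )
}

#' @export
print.stepped_binding_model <- function(x, ...) {
  cat(sprintf("<stepped_binding_model> %s: %d Zn(II) sites\n",
              x$name, x$n_sites))
  cat("  -logKd steps (tightest first):",
      paste(format(x$pkd_steps), collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative log10 association constants
#'
#' Adair bookkeeping: `log10 beta_i = sum_{j<=i} pkd_j`, so that the
#' concentration of the `Zn_i` species is proportional to
#' `beta_i * [Zn]^i`.
#'
#' @param model A [binding_model()].
#' @return Numeric vector of length `n_sites` of `log10 beta_i`.
#' @export
cumulative_log_betas <- function(model) {
  stopifnot(inherits(model, "stepped_binding_model"))
  cumsum(model$pkd_steps)
}

#' 1:1 chelator
#'
#' A small-molecule ligand forming a 1:1 Zn(II) complex with apparent
#' dissociation constant `10^-pkd` M at the working pH.
#'
#' @param name Text label.
#' @param pkd `-log10` apparent dissociation constant (molar).
#' @return An object of class `chelator_1to1`.
#' @export
chelator <- function(name, pkd) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(pkd), length(pkd) == 1L, is.finite(pkd))
  structure(list(name = name, pkd = pkd), class = "chelator_1to1")
}

#' 2:1 chromogenic probe (PAR-type)
#'
#' A ligand forming a 2:1 (ligand:metal) chromophoric complex. `kd12` is
#' the overall dissociation constant of the bis-ligand complex
#' (`[Zn][L]^2 / [ZnL2]`, units M^2); protonated ligand microstates are
#' subsumed in this conditional constant. The complex absorbance follows
#' Beer-Lambert with `epsilon_492`.
#'
#' @param name Text label.
#' @param kd12 Overall dissociation constant of the ZnL2 complex, M^2.
#' @param epsilon_492 Molar absorptivity of the complex, M^-1 cm^-1.
#' @param path_length Optical path, cm.
#' @return An object of class `probe_2to1`.
#' @export
probe_2to1 <- function(name = "PAR", kd12 = 7.1e-13, epsilon_492 = 71500,
                       path_length = 1) {
  stopifnot(is.numeric(kd12), kd12 > 0, is.numeric(epsilon_492),
            epsilon_492 > 0, is.numeric(path_length), path_length > 0)
  structure(list(name = name, kd12 = kd12, epsilon_492 = epsilon_492,
                 path_length = path_length),
            class = "probe_2to1")
}

#' 1:1 fluorescent probe (ZnAF-type)
#'
#' @param name Text label.
#' @param pkd `-log10` apparent dissociation constant (molar); the default
#'   corresponds to Kd = 5.5 nM.
#' @return An object of class `probe_1to1`.
#' @export
probe_1to1 <- function(name = "ZnAF-2F", pkd = -log10(5.5e-9)) {
  stopifnot(is.numeric(pkd), length(pkd) == 1L, is.finite(pkd))
  structure(list(name = name, pkd = pkd), class = "probe_1to1")
}

#' Map dissociation-order site indices onto association-order steps
#'
#' Competition tables commonly index constants from the holo protein
#' (their "Kd1" is the first ion to dissociate, i.e. the weakest site)
#' while this package's step `i` counts association order (tightest
#' first). The two indexings are related by
#' `dissociation index i <-> step n_sites + 1 - i`. Exposing the
#' conversion explicitly prevents a silent off-by-one.
#'
#' @param model A [binding_model()].
#' @return A data.frame with columns `dissociation_index`, `step`,
#'   `pkd` (the shared constant).
#' @export
dissociation_order_index <- function(model) {
  stopifnot(inherits(model, "stepped_binding_model"))
  n <- model$n_sites
  data.frame(
    dissociation_index = seq_len(n),
    step = n + 1L - seq_len(n),
    pkd = model$pkd_steps[n + 1L - seq_len(n)]
  )
}

# log10(10^la + 10^lb) without overflow
log10_add <- function(la, lb) {
  if (la == -Inf) return(lb)
  if (lb == -Inf) return(la)
  m <- max(la, lb)
  m + log10(10^(la - m) + 10^(lb - m))
}

#' Macroscopic model of independent binding sites
#'
#' Composes `n` independent 1:1 sites with per-site `-log10 Kd` values
#' into the equivalent macroscopic stepwise model: the cumulative
#' association constants are the elementary symmetric polynomials of the
#' site association constants, `beta_i = e_i(1/K_1, ..., 1/K_n)`,
#' evaluated in log10 space, and the stepwise constants are their
#' successive ratios. For equal sites this is the usual statistical
#' factor ladder (`Kd_step_i = Kd * i / (n - i + 1)`), and the model's
#' [mean_occupancy()] divided by `n_sites` equals `z / (z + Kd)`
#' exactly. Useful as a generator whose site constants an estimator of
#' independent-site form should recover.
#'
#' @param name Text label.
#' @param site_pkds Per-site `-log10 Kd` values (any order).
#' @return A [binding_model()]; the site constants are kept in
#'   `attr(, "site_pkds")`.
#' @export
independent_sites_model <- function(name, site_pkds) {
  site_pkds <- as.numeric(site_pkds)
  stopifnot(length(site_pkds) >= 1L, all(is.finite(site_pkds)))
  n <- length(site_pkds)
  le <- c(0, rep(-Inf, n))          # log10 elementary symmetric polys
  for (lx in site_pkds) {
    for (i in (n + 1L):2L)
      le[i] <- log10_add(le[i], le[i - 1L] + lx)
  }
  log_betas <- le[-1L]
  steps <- diff(c(0, log_betas))
  steps <- sort(steps, decreasing = TRUE)   # guard FP ties
  m <- binding_model(name, steps)
  attr(m, "site_pkds") <- sort(site_pkds, decreasing = TRUE)
  m
}
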