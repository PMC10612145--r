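#' Kinetic trace of chromophore appearance
#'
#' One absorbance-versus-time trace (e.g. TNB- appearance at 412 nm
#' during thiol oxidation).
#'
#' @param time Time, s; strictly increasing, >= 5 points.
#' @param signal Absorbance at each time point.
#' @param metadata Optional named list (protein, Zn eq, chelator, ...).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, signal, metadata = list()) {
  stopifnot(is.numeric(time), is.numeric(signal),
            length(time) == length(signal))
  if (length(time) < 5L) stop("need >= 5 time points", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("'time' must be strictly increasing", call. = FALSE)
  structure(list(time = time, signal = signal, metadata = metadata),
            class = "kinetic_trace")
}

#' Pseudo-first-order fit of a kinetic trace
#'
#' Least squares of `A(t) = A0 + A_amp (1 - exp(-k t))`. The baseline
#' `A0` is fitted, not forced to zero. The fitted rate is invariant to
#' uniform signal scaling (amplitude scales instead). A flat or
#' non-monotone trace yields `converged = FALSE` with a diagnostic flag.
#'
#' @param trace A [kinetic_trace()].
#' @return A [fit_result()] with parameters `k_obsd` (s^-1),
#'   `amplitude`, `offset`.
#' @export
fit_pseudo_first_order <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  d <- data.frame(t = trace$time, a = trace$signal)
  rng <- diff(range(d$a))
  if (rng <= 0 || rng < 1e-12 * max(abs(d$a), 1))
    return(fit_result(c(k_obsd = NA_real_, amplitude = NA_real_,
                        offset = NA_real_),
                      converged = FALSE, model_tag = "pseudo_first_order",
                      flags = "flat trace: no amplitude to fit"))
  # crude initial rate: time to reach half the observed span
  half_t <- d$t[which.min(abs(d$a - (min(d$a) + rng / 2)))]
  k0 <- if (half_t > 0) log(2) / half_t else 1 / max(d$t)
  res <- nls_fit_result(
    a ~ a0 + amp * (1 - exp(-k * t)),
    data = d,
    start = list(a0 = d$a[1], amp = rng, k = k0),
    model_tag = "pseudo_first_order",
    lower = c(-Inf, -Inf, 1e-12), upper = c(Inf, Inf, Inf))
  if (!res$converged) return(res)
  est <- res$parameters; se <- res$standard_errors
  fit_result(c(k_obsd = unname(est["k"]), amplitude = unname(est["amp"]),
               offset = unname(est["a0"])),
             c(k_obsd = unname(se["k"]), amplitude = unname(se["amp"]),
               offset = unname(se["a0"])),
             residual_norm = res$residual_norm, converged = TRUE,
             model_tag = "pseudo_first_order")
}

# Continuous piecewise-linear least squares at fixed knots via the
# truncated-line basis; returns fit and RSS.
pwl_fit <- function(x, y, knots) {
  X <- cbind(1, x)
  for (k in knots) X <- cbind(X, pmax(x - k, 0))
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

#' Breakpoints of a titration profile
#'
#' Continuous piecewise-linear least squares with `n_breaks` free knots:
#' knot positions are grid-initialized over the interior of the observed
#' x-range and refined by local optimization. Returns knot positions
#' (ties broken toward smaller x) and per-segment slopes. A profile in
#' which the best piecewise fit improves on a single line by a
#' negligible margin is flagged unidentifiable.
#'
#' @param points data.frame with columns `x` (e.g. Zn(II) mol eq) and
#'   `y` (k_obsd or absorbance); needs `>= 2 * (n_breaks + 1)` points.
#' @param n_breaks 1 or 2 knots.
#' @return A [fit_result()] with parameters `knot1` (and `knot2`) plus
#'   `slope1..slope(n_breaks+1)`.
#' @export
titration_endpoints <- function(points, n_breaks = 1L) {
  d <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(d)), n_breaks %in% 1:2)
  d <- d[order(d$x), ]
  if (nrow(d) < 2L * (n_breaks + 1L))
    stop(sprintf("need >= %d points for %d breakpoint(s)",
                 2L * (n_breaks + 1L), n_breaks), call. = FALSE)
  x <- d$x; y <- d$y
  interior <- c(x[2L] + 1e-9, x[length(x) - 1L] - 1e-9)
  cand <- seq(interior[1L], interior[2L], length.out = 60L)

  obj <- function(knots) {
    knots <- sort(knots)
    if (any(knots <= interior[1L] - 1e-9) || any(knots >= interior[2L] + 1e-9))
      return(Inf)
    if (n_breaks == 2L && diff(knots) < 1e-9) return(Inf)
    pwl_fit(x, y, knots)$rss
  }

  if (n_breaks == 1L) {
    rss <- vapply(cand, obj, numeric(1))
    k0 <- min(cand[rss <= min(rss) + 1e-15])   # ties toward smaller x
    op <- stats::optimize(obj, lower = max(interior[1L], k0 - diff(interior) / 20),
                          upper = min(interior[2L], k0 + diff(interior) / 20),
                          tol = 1e-10)
    knots <- op$minimum
    if (op$objective > obj(k0)) knots <- k0
  } else {
    grid2 <- expand.grid(k1 = cand, k2 = cand)
    grid2 <- grid2[grid2$k2 > grid2$k1 + 1e-9, ]
    rss <- mapply(function(a, b) obj(c(a, b)), grid2$k1, grid2$k2)
    ix <- which(rss <= min(rss) + 1e-15)
    ix <- ix[order(grid2$k1[ix], grid2$k2[ix])][1L]
    k0 <- c(grid2$k1[ix], grid2$k2[ix])
    op <- stats::optim(k0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12))
    knots <- sort(if (op$value <= obj(k0)) op$par else k0)
  }
  best <- pwl_fit(x, y, knots)
  base <- pwl_fit(x, y, numeric(0))
  unident <- (base$rss - best$rss) <= 1e-10 * max(base$rss, 1e-30) ||
    base$rss < 1e-20 * max(sum(y^2), 1)
  slopes <- cumsum(best$coef[-1L])
  pars <- c(stats::setNames(knots, paste0("knot", seq_len(n_breaks))),
            stats::setNames(slopes, paste0("slope", seq_along(slopes))))
  fit_result(pars, residual_norm = best$rss,
             converged = TRUE, model_tag = "titration_endpoints",
             flags = if (unident) "unidentifiable: single line fits as well"
                     else character(0))
}

#' Regression of oxidation rate on chelator affinity
#'
#' Ordinary least squares of `log10 k_obsd` against the chelator's
#' `-logKd`: the linearity (and slope) of this relation summarizes how
#' strongly mobilizing the weakest sites accelerates thiol oxidation.
#'
#' @param points data.frame with columns `chelator_pkd` and
#'   `log10_k_obsd` (>= 3 points, >= 2 distinct abscissae).
#' @return A [fit_result()] with parameters `slope`, `intercept`,
#'   `r_squared`.
#' @export
chelator_rate_regression <- function(points) {
  d <- as.data.frame(points)
  stopifnot(all(c("chelator_pkd", "log10_k_obsd") %in% names(d)))
  if (nrow(d) < 3L) stop("need >= 3 points", call. = FALSE)
  if (length(unique(d$chelator_pkd)) < 2L)
    stop("rank deficient: need >= 2 distinct chelator pkd values",
         call. = FALSE)
  fit <- stats::lm(log10_k_obsd ~ chelator_pkd, data = d)
  s <- summary(fit)
  co <- s$coefficients
  fit_result(
    c(slope = unname(co["chelator_pkd", "Estimate"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      r_squared = s$r.squared),
    c(slope = unname(co["chelator_pkd", "Std. Error"]),
      intercept = unname(co["(Intercept)", "Std. Error"]),
      r_squared = NA_real_),
    residual_norm = sum(stats::resid(fit)^2), converged = TRUE,
    model_tag = "chelator_rate_regression")
}
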