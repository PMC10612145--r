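#' Construct a fit result
#'
#' Common container returned by every estimator: named parameter
#' estimates (on `-log10` molar scale where applicable), standard
#' errors, residual norm, convergence flag and a model tag. Extra fields
#' (flags, diagnostics) are carried through `...`.
#'
#' @param parameters Named numeric vector of estimates.
#' @param standard_errors Named numeric vector (NA where unavailable).
#' @param residual_norm Residual sum of squares (or equivalent).
#' @param converged Logical.
#' @param model_tag Short text identifying the model fitted.
#' @param ... Further named diagnostic fields.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(parameters, standard_errors = NULL,
                       residual_norm = NA_real_, converged = TRUE,
                       model_tag = "", ...) {
  if (is.null(standard_errors)) {
    standard_errors <- rep(NA_real_, length(parameters))
    names(standard_errors) <- names(parameters)
  }
  if (isTRUE(converged) &&
      (any(!is.finite(parameters))))
    stop("a converged fit_result requires finite parameters", call. = FALSE)
  structure(c(list(parameters = parameters,
                   standard_errors = standard_errors,
                   residual_norm = residual_norm,
                   converged = isTRUE(converged),
                   model_tag = model_tag),
              list(...)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s)\n", x$model_tag,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = x$parameters, se = x$standard_errors)
  print(tab)
  if (is.finite(x$residual_norm))
    cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  flags <- x$flags
  if (!is.null(flags) && length(flags))
    cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

# Wrap an nlsLM fit into a fit_result; non-convergence is reported, not
# raised.
nls_fit_result <- function(formula, data, start, model_tag,
                           lower = -Inf, upper = Inf) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    p <- unlist(start) * NA_real_
    return(fit_result(p, residual_norm = NA_real_, converged = FALSE,
                      model_tag = model_tag,
                      flags = "non-convergence",
                      message = conditionMessage(fit)))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  fit_result(est, se, residual_norm = sum(stats::resid(fit)^2),
             converged = TRUE, model_tag = model_tag, fit = fit)
}
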