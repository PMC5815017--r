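#' Express responses as a percentage of the theoretical maximum
#'
#' SPR responses are normalised to the theoretical maximum response Rmax for
#' 1:1 stoichiometry (one protein dimer per immobilised DNA duplex), which
#' makes responses comparable across chip surfaces irrespective of the amount
#' and length of tethered DNA.
#'
#' @param responses response values (RU).
#' @param rmax theoretical maximum response (> 0, RU).
#' @return Percentages (`100 * response / rmax`).
#' @export
percent_rmax <- function(responses, rmax) {
  if (rmax <= 0) stop("rmax must be > 0")
  100 * responses / rmax
}

#' 1:1 Langmuir isotherm response
#'
#' Equilibrium response of a 1:1 interaction at analyte concentration `c`:
#' `rmax * c / (kd + c)`.
#'
#' @param kd dissociation constant (> 0), in the concentration's units.
#' @param rmax maximal response (RU).
#' @param concentration analyte concentration(s) (>= 0).
#' @return Predicted response(s).
#' @export
predict_response <- function(kd, rmax, concentration) {
  if (kd <= 0) stop("kd must be > 0")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  rmax * concentration / (kd + concentration)
}

#' Fit the dissociation constant from an equilibrium titration
#'
#' Unweighted nonlinear least squares of the 1:1 isotherm
#' `R(c) = rmax * c / (kd + c)` over `(kd, rmax)`, both constrained positive.
#' Initial values: `kd` at the concentration whose response is nearest half
#' the maximum observed response; `rmax` at 1.1x the maximum response.
#' Non-convergence is reported via `converged = FALSE` with the optimiser
#' message, never as a silent bad fit.
#'
#' @param series a titration `data.frame` with columns `concentration_nM` and
#'   `response_RU` (>= 3 distinct positive concentrations).
#' @return An object of class `kd_fit`: `kd` (nM), `rmax` (RU),
#'   `residual_sum_of_squares`, `standard_error_kd`, `converged`, `message`,
#'   and the underlying `fit` object.
#' @export
fit_kd <- function(series) {
  conc <- series$concentration_nM
  resp <- series$response_RU
  if (length(conc) != length(resp) || length(conc) < 3)
    stop("titration needs >= 3 concentration/response pairs")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (anyDuplicated(conc)) stop("concentrations must be distinct")
  if (all(resp == 0)) stop("responses are all zero: no binding signal to fit")
  half <- max(resp) / 2
  kd0 <- conc[which.min(abs(resp - half))]
  rmax0 <- 1.1 * max(resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ rmax * conc / (kd + conc),
      start = list(kd = kd0, rmax = rmax0),
      lower = c(kd = .Machine$double.eps, rmax = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(kd = NA_real_, rmax = NA_real_,
                          residual_sum_of_squares = NA_real_,
                          standard_error_kd = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "kd_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(kd = unname(cf["kd"]), rmax = unname(cf["rmax"]),
                 residual_sum_of_squares = stats::deviance(fit),
                 standard_error_kd = unname(se),
                 converged = isTRUE(fit$convInfo$isConv),
                 message = fit$convInfo$stopMessage, fit = fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged && is.na(x$kd)) {
    cat("<kd_fit> did not converge:", x$message, "\n")
  } else {
    cat(sprintf("<kd_fit> Kd = %.4g nM (se %.3g), Rmax = %.4g RU, RSS = %.3g%s\n",
                x$kd, x$standard_error_kd, x$rmax,
                x$residual_sum_of_squares,
                if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}
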