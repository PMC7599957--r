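#' @describeIn CholModel-class compact network summary
#' @param object a \code{CholModel}
#' @export
setMethod("show", "CholModel", function(object) {
  sp <- object@species
  cat(sprintf("CholModel: %d reactions, %d dynamic + %d boundary species\n",
              length(object@reactions), sum(sp$role == "dynamic"),
              sum(sp$role == "boundary")))
  if (length(object@reactions)) {
    laws <- table(vapply(object@reactions, `[[`, character(1), "rate_law"))
    cat("rate laws:", paste(sprintf("%s (%d)", names(laws), laws),
                            collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @describeIn ParameterSet-class constants with provenance summary
#' @param object a \code{ParameterSet}
#' @export
setMethod("show", "ParameterSet", function(object) {
  pv <- table(object@provenance)
  cat(sprintf("ParameterSet: %d constants (%s), %d initial concentrations\n",
              length(object@constants),
              paste(sprintf("%d %s", pv, names(pv)), collapse = ", "),
              length(object@initial)))
  invisible(NULL)
})

#' @describeIn Trajectory-class time range and species count
#' @param object a \code{Trajectory}
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] min, %d species\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@states)))
  invisible(NULL)
})

#' @describeIn SteadyStateResult-class convergence and stability verdict
#' @param object a \code{SteadyStateResult}
#' @export
setMethod("show", "SteadyStateResult", function(object) {
  cat(sprintf(
    "SteadyStateResult: %s (residual %.3g, method %s), %s\n",
    if (object@converged) "converged" else "NOT converged",
    object@residual_norm, object@method,
    if (object@stable) "asymptotically stable (all Re(lambda) < 0)"
    else "not asymptotically stable"))
  invisible(NULL)
})

#' @describeIn ControlCoefficients-class dimensions and theorem residuals
#' @param object a \code{ControlCoefficients}
#' @export
setMethod("show", "ControlCoefficients", function(object) {
  ok <- !object@flags$failed
  fres <- max(abs(rowSums(object@flux_cc[, ok, drop = FALSE]) - 1), na.rm = TRUE)
  cres <- max(abs(rowSums(object@conc_cc[, ok, drop = FALSE])), na.rm = TRUE)
  cat(sprintf(
    "ControlCoefficients (%s, delta %.1g): %d fluxes x %d steps, %d species\n",
    object@method, object@delta, nrow(object@flux_cc), ncol(object@flux_cc),
    nrow(object@conc_cc)))
  cat(sprintf("max |summation residual|: flux %.3g, concentration %.3g\n",
              fres, cres))
  invisible(NULL)
})

#' @describeIn ScanResult-class grid shape and readout
#' @param object a \code{ScanResult}
#' @export
setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d grid points (%s), readout %g min, observables: %s\n",
              nrow(object@grid),
              paste(names(object@spec$axes), collapse = " x "),
              object@spec$readout_time,
              paste(object@spec$observables, collapse = ", ")))
  if (any(!object@grid$ok))
    cat(sprintf("  %d flagged (failed) cells\n", sum(!object@grid$ok)))
  invisible(NULL)
})

#' @describeIn CalibrationResult-class fit summary
#' @param object a \code{CalibrationResult}
#' @export
setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: %d free constant(s), %s, objective %.4g, max |rel err| %.3g%%\n",
    length(object@free),
    if (object@converged) "converged" else "not converged",
    object@objective, 100 * max(abs(object@residuals$rel_error))))
  invisible(NULL)
})
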