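#' Integrate the model in time
#'
#' Stiff integration (\code{deSolve::lsoda}) of the dynamic species from the
#' initial state in \code{params}, with an analytic Jacobian assembled from
#' the rate-law derivatives. Default tolerances are rtol 1e-8 / atol 1e-10;
#' the readout time \code{t_end} is always included in the output grid.
#' Negativity is policed, not clipped: any excursion below -1e-12 aborts
#' with a diagnostic naming the first failing species.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param t_end final time (minutes), > 0.
#' @param record_times optional numeric vector of output times; \code{0} and
#'   \code{t_end} are added if absent.
#' @param rtol,atol solver tolerances.
#' @return a [Trajectory-class]; \code{fluxes_at_readout} holds the 30
#'   reaction rates at \code{t_end}.
#' @examples
#' f <- makeFixture("tiny_chain")
#' tr <- simulateModel(f$model, f$params, t_end = 100)
#' tail(tr@states, 1)
#' @export
simulateModel <- function(model, params, t_end, record_times = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  if (!is.numeric(t_end) || t_end <= 0)
    stop("t_end must be > 0")
  comp <- .compileModel(model, params)
  times <- sort(unique(c(0, record_times, t_end)))
  times <- times[times <= t_end & times >= 0]
  out <- .integrate(comp, comp$conc0[comp$dynIdx], times, rtol, atol)
  states <- out[, -1, drop = FALSE]
  colnames(states) <- comp$dynIds
  vT <- .ratesFromConc(comp, .fullConc(comp, states[nrow(states), ]))
  new("Trajectory", times = out[, 1], states = states,
      fluxes_at_readout = setNames(vT, comp$rxIds))
}

## core integrator over a compiled model; returns the deSolve matrix
.integrate <- function(comp, y0, times, rtol = 1e-8, atol = 1e-10) {
  ndyn <- length(comp$dynIdx)
  rhs <- function(t, y, p) {
    bad <- which(y < -1e-12)
    if (length(bad))
      stop(sprintf("integration produced a negative concentration for %s at t = %g",
                   comp$dynIds[bad[1]], t))
    conc <- comp$conc0
    conc[comp$dynIdx] <- y
    list(as.numeric(comp$N %*% .ratesFromConc(comp, conc)))
  }
  jac <- function(t, y, p) {
    conc <- comp$conc0
    conc[comp$dynIdx] <- y
    E <- .unscaledElasticities(comp, conc)
    comp$N %*% E[, comp$dynIdx, drop = FALSE]
  }
  out <- try(deSolve::lsoda(y = as.numeric(y0), times = times, func = rhs,
                            parms = NULL, jacfunc = jac, jactype = "fullusr",
                            rtol = rtol, atol = atol, maxsteps = 50000),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop(sprintf("integration failed: %s", attr(out, "condition")$message))
  if (nrow(out) < length(times))
    stop("integration failed before reaching t_end (stiffness or blow-up)")
  unclass(out)
}

## fast path: named dynamic state at t_end only
.simulateReadout <- function(comp, t_end, rtol = 1e-8, atol = 1e-10) {
  out <- .integrate(comp, comp$conc0[comp$dynIdx], c(0, t_end), rtol, atol)
  setNames(out[nrow(out), -1], comp$dynIds)
}
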