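#' Jacobian of the ODE right-hand side
#'
#' Entry (i, j) is the partial derivative of d[s_i]/dt with respect to s_j,
#' over dynamic species. The default uses central finite differences with a
#' configurable relative step; \code{method = "analytic"} assembles the
#' exact Jacobian from the closed-form derivatives of every rate law and
#' serves as an independent cross-check.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param state non-negative dynamic state (named or in model order).
#' @param method "finite_difference" (default) or "analytic".
#' @param rel_step relative step for the finite-difference method.
#' @return square matrix with species-id dimnames.
#' @examples
#' f <- makeFixture("tiny_chain")
#' modelJacobian(f$model, f$params, c(A = 1, B = 1, C = 1))
#' @export
modelJacobian <- function(model, params, state,
                          method = c("finite_difference", "analytic"),
                          rel_step = 1e-6) {
  method <- match.arg(method)
  comp <- .compileModel(model, params)
  conc <- .fullConc(comp, state)
  y <- conc[comp$dynIdx]
  .checkNonNegative(comp, y)
  n <- length(y)
  if (method == "analytic") {
    E <- .unscaledElasticities(comp, conc)
    J <- comp$N %*% E[, comp$dynIdx, drop = FALSE]
  } else {
    f <- function(yy) {
      cc <- comp$conc0
      cc[comp$dynIdx] <- yy
      as.numeric(comp$N %*% .ratesFromConc(comp, cc))
    }
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- rel_step * max(abs(y[j]), 1e-8)
      yp <- y; yp[j] <- y[j] + h
      ym <- y; ym[j] <- y[j] - h
      J[, j] <- (f(yp) - f(ym)) / (2 * h)
    }
  }
  dimnames(J) <- list(comp$dynIds, comp$dynIds)
  J
}

#' Locate a steady state and classify its stability
#'
#' Damped Newton iteration on the right-hand side (with the analytic
#' Jacobian), falling back to long-time integration to improve the starting
#' point when Newton stalls. Stability is read off the spectrum of the
#' Jacobian restricted to dynamic species: asymptotically stable iff all
#' eigenvalue real parts are negative.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param initial_guess optional non-negative starting state; defaults to
#'   the initial concentrations in \code{params}.
#' @param tol residual tolerance: convergence requires max |d/dt| below it.
#' @param max_iter Newton iteration budget per attempt.
#' @return a [SteadyStateResult-class]; \code{converged = FALSE} (never a
#'   silent partial answer) if the budget is exhausted.
#' @examples
#' f <- makeFixture("tiny_chain")
#' ss <- findSteadyState(f$model, f$params)
#' ss@state  # A = k_in/k_ab etc.
#' @export
findSteadyState <- function(model, params, initial_guess = NULL,
                            tol = 1e-6, max_iter = 50) {
  comp <- .compileModel(model, params)
  y <- if (is.null(initial_guess)) comp$conc0[comp$dynIdx]
       else .fullConc(comp, initial_guess)[comp$dynIdx]
  .checkNonNegative(comp, y)

  f <- function(yy) {
    cc <- comp$conc0
    cc[comp$dynIdx] <- yy
    as.numeric(comp$N %*% .ratesFromConc(comp, cc))
  }
  jacAt <- function(yy) {
    cc <- comp$conc0
    cc[comp$dynIdx] <- yy
    E <- .unscaledElasticities(comp, cc)
    comp$N %*% E[, comp$dynIdx, drop = FALSE]
  }
  newton <- function(y) {
    for (i in seq_len(max_iter)) {
      r <- f(y)
      if (max(abs(r)) < tol) return(list(y = y, ok = TRUE))
      step <- try(solve(jacAt(y), -r), silent = TRUE)
      if (inherits(step, "try-error")) return(list(y = y, ok = FALSE))
      lambda <- 1
      repeat {
        yn <- y + lambda * step
        if (all(yn >= 0)) {
          rn <- f(yn)
          if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) break
        }
        lambda <- lambda / 2
        if (lambda < 1e-6) return(list(y = y, ok = FALSE))
      }
      y <- yn
    }
    list(y = y, ok = max(abs(f(y))) < tol)
  }

  method <- "newton"
  res <- newton(y)
  t_relax <- 1e4
  while (!res$ok && t_relax <= 1e6) {
    method <- "integration+newton"
    out <- try(.integrate(comp, res$y, c(0, t_relax)), silent = TRUE)
    if (!inherits(out, "try-error")) res$y <- pmax(out[nrow(out), -1], 0)
    res <- newton(res$y)
    t_relax <- t_relax * 10
  }
  y <- res$y
  resid <- max(abs(f(y)))
  J <- jacAt(y)
  ev <- eigen(J, only.values = TRUE)$values
  new("SteadyStateResult",
      state = setNames(as.numeric(y), comp$dynIds),
      fluxes = {
        cc <- comp$conc0; cc[comp$dynIdx] <- y
        setNames(.ratesFromConc(comp, cc), comp$rxIds)
      },
      residual_norm = resid,
      stable = all(Re(ev) < 0),
      eigenvalues = as.complex(ev),
      converged = resid < tol,
      method = method)
}
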