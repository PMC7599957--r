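## Metabolic control analysis at steady state.
##
## Scaled control coefficients follow the classical definitions: the flux
## control coefficient C_i^J = dln(J)/dln(v_i) and the concentration control
## coefficient C_i^S = dln(S)/dln(v_i), where "perturbing step i" means
## scaling its whole rate expression by (1 + delta) — the activity
## normalisation that makes the summation theorems (sum_i C_i^J = 1,
## sum_i C_i^S = 0) hold.  Two independent routes are provided: re-solving
## the steady state under explicit +/-delta activity perturbations (default),
## and the elasticity/matrix method on the (reduced) stoichiometry.

## compile with per-reaction activity scaling factors
.compileScaled <- function(model, params, scale) {
  comp <- .compileModel(model, params)
  comp$scale <- scale
  comp
}

.scaledRates <- function(comp, conc) {
  v <- .ratesFromConc(comp, conc)
  if (!is.null(comp$scale)) v <- v * comp$scale
  v
}

## Newton re-solve under per-reaction activity scaling.  Perturbations of
## low-flux steps move the residual by far less than any absolute residual
## tolerance, so convergence is judged on the relative Newton step instead.
.ssForScale <- function(model, params, scale, guess, step_tol = 1e-11) {
  comp <- .compileModel(model, params)
  f <- function(yy) {
    cc <- comp$conc0
    cc[comp$dynIdx] <- yy
    as.numeric(comp$N %*% (.ratesFromConc(comp, cc) * scale))
  }
  jacAt <- function(yy) {
    cc <- comp$conc0
    cc[comp$dynIdx] <- yy
    E <- .unscaledElasticities(comp, cc) * scale
    comp$N %*% E[, comp$dynIdx, drop = FALSE]
  }
  y <- guess
  done <- FALSE
  for (i in 1:60) {
    r <- f(y)
    step <- try(solve(jacAt(y), -r), silent = TRUE)
    if (inherits(step, "try-error")) return(list(ok = FALSE))
    relstep <- max(abs(step) / pmax(abs(y), 1e-12))
    yn <- y + step
    if (any(yn < 0) || any(!is.finite(yn))) {
      lambda <- 0.5
      repeat {
        yn <- y + lambda * step
        if (all(yn >= 0) && all(is.finite(yn))) break
        lambda <- lambda / 2
        if (lambda < 1e-8) return(list(ok = FALSE))
      }
    }
    y <- yn
    if (relstep < step_tol) {
      done <- TRUE
      break
    }
  }
  if (!done) return(list(ok = FALSE))
  cc <- comp$conc0
  cc[comp$dynIdx] <- y
  list(state = y, fluxes = .ratesFromConc(comp, cc) * scale, ok = TRUE)
}

#' Scaled elasticity matrix at a steady state
#'
#' \eqn{\epsilon_{r,s} = \partial \ln v_r / \partial \ln s} for every
#' reaction r and dynamic species s, evaluated at the steady state by
#' central differences on log-concentration (relative step 1e-3 by
#' default). Entries whose reference flux or concentration is zero are
#' undefined: they are returned as NA and flagged in the
#' \code{"undefined"} attribute, never silently zeroed.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param steady_state a converged [SteadyStateResult-class].
#' @param rel_step relative perturbation of each concentration.
#' @param method "finite_difference" (default) or "analytic" (closed-form
#'   rate-law derivatives; the cross-check oracle).
#' @return matrix (reactions x dynamic species) with an \code{"undefined"}
#'   logical matrix attribute.
#' @export
elasticityMatrix <- function(model, params, steady_state, rel_step = 1e-3,
                             method = c("finite_difference", "analytic")) {
  method <- match.arg(method)
  stopifnot(is(steady_state, "SteadyStateResult"))
  if (!steady_state@converged)
    stop("elasticities require a converged steady state")
  comp <- .compileModel(model, params)
  s0 <- steady_state@state[comp$dynIds]
  v0 <- steady_state@fluxes
  conc <- .fullConc(comp, s0)
  n <- length(s0)
  E <- matrix(NA_real_, comp$nr, n, dimnames = list(comp$rxIds, comp$dynIds))
  if (method == "analytic") {
    Eu <- .unscaledElasticities(comp, conc)[, comp$dynIdx, drop = FALSE]
    E <- Eu * outer(1 / v0, s0)
  } else {
    for (j in seq_len(n)) {
      if (s0[j] == 0) next
      h <- rel_step * s0[j]
      cp <- conc; cp[comp$dynIdx[j]] <- s0[j] + h
      cm <- conc; cm[comp$dynIdx[j]] <- s0[j] - h
      dv <- (.ratesFromConc(comp, cp) - .ratesFromConc(comp, cm)) / (2 * h)
      E[, j] <- dv * s0[j] / v0
    }
  }
  undef <- outer(v0 == 0, rep(TRUE, n)) | outer(rep(TRUE, comp$nr), s0 == 0)
  E[undef] <- NA_real_
  dimnames(E) <- list(comp$rxIds, comp$dynIds)
  attr(E, "undefined") <- undef
  E
}

## matrix-method control coefficients from analytic elasticities
.mcaMatrixMethod <- function(model, params, steady_state) {
  comp <- .compileModel(model, params)
  s0 <- steady_state@state[comp$dynIds]
  v0 <- steady_state@fluxes
  conc <- .fullConc(comp, s0)
  Eu <- .unscaledElasticities(comp, conc)[, comp$dynIdx, drop = FALSE]
  N <- comp$N
  ## detect conserved moieties (rank deficiency) and reduce via the link
  ## matrix L (N = L N_R) when present
  qrN <- qr(t(N))
  rk <- qrN$rank
  if (rk < nrow(N)) {
    keep <- sort(qrN$pivot[seq_len(rk)])
    NR <- N[keep, , drop = FALSE]
    L <- t(solve(tcrossprod(NR), NR %*% t(N)))   # n x rk, N = L %*% NR
    MR <- NR %*% Eu %*% L
    GR <- -solve(MR, NR %*% diag(v0))
    G <- L %*% GR
  } else {
    M <- N %*% Eu                     # Jacobian
    ## unscaled concentration response to scaling reaction j: -M^{-1} N v_j e_j
    G <- -solve(M, N %*% diag(v0))    # dS/d(ln activity_j)
  }
  dv <- Eu %*% G + diag(v0)           # dv_k/d(ln activity_j)
  conc_cc <- G / s0                   # rows species, cols steps
  flux_cc <- dv / v0
  dimnames(conc_cc) <- list(comp$dynIds, comp$rxIds)
  dimnames(flux_cc) <- list(comp$rxIds, comp$rxIds)
  list(conc_cc = conc_cc, flux_cc = flux_cc)
}

## finite-difference control coefficients: re-solve steady state at
## activities scaled by (1 +/- delta), central log-ratio
.mcaFiniteDifference <- function(model, params, steady_state, delta) {
  comp <- .compileModel(model, params)
  nr <- comp$nr
  n <- length(comp$dynIds)
  s0 <- steady_state@state[comp$dynIds]
  v0 <- steady_state@fluxes
  conc_cc <- matrix(NA_real_, n, nr, dimnames = list(comp$dynIds, comp$rxIds))
  flux_cc <- matrix(NA_real_, nr, nr, dimnames = list(comp$rxIds, comp$rxIds))
  failed <- setNames(rep(FALSE, nr), comp$rxIds)
  dlog <- log(1 + delta) - log(1 - delta)
  for (j in seq_len(nr)) {
    sc_p <- sc_m <- rep(1, nr)
    sc_p[j] <- 1 + delta
    sc_m[j] <- 1 - delta
    up <- .ssForScale(model, params, sc_p, s0)
    dn <- .ssForScale(model, params, sc_m, s0)
    if (!up$ok || !dn$ok) {
      failed[j] <- TRUE
      next
    }
    conc_cc[, j] <- log(up$state / dn$state) / dlog
    flux_cc[, j] <- log(up$fluxes / dn$fluxes) / dlog
  }
  ## zero reference values are undefined on the log scale
  conc_cc[s0 == 0, ] <- NA_real_
  flux_cc[v0 == 0, ] <- NA_real_
  list(conc_cc = conc_cc, flux_cc = flux_cc, failed = failed)
}

#' Flux control coefficients
#'
#' Computes the full matrix of scaled flux control coefficients
#' \eqn{C_i^J} at a converged, stable steady state. The default
#' finite-difference route scales each step's activity by \eqn{1 \pm
#' \delta}, re-solves the steady state, and forms the central log-ratio;
#' \code{method = "matrix"} uses the elasticity-based matrix method and is
#' the independent cross-check. Steps whose perturbed steady state fails to
#' re-solve are flagged (NA column) with a warning.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param steady_state a converged stable [SteadyStateResult-class]; if
#'   missing it is computed.
#' @param delta relative activity perturbation (default 1e-3).
#' @param method "finite_difference" or "matrix".
#' @return a [ControlCoefficients-class] (conc_cc filled as well; the two
#'   matrices are always computed together).
#' @examples
#' f <- makeFixture("tiny_chain")
#' cc <- fluxControlCoefficients(f$model, f$params)
#' rowSums(cc@flux_cc)  # summation theorem: all 1
#' @export
fluxControlCoefficients <- function(model, params, steady_state = NULL,
                                    delta = 1e-3,
                                    method = c("finite_difference", "matrix")) {
  method <- match.arg(method)
  if (is.null(steady_state))
    steady_state <- findSteadyState(model, params)
  stopifnot(is(steady_state, "SteadyStateResult"))
  if (!steady_state@converged)
    stop("control coefficients require a converged steady state")
  if (!steady_state@stable)
    warning("steady state is not asymptotically stable; control coefficients may be meaningless")
  if (method == "matrix") {
    mm <- .mcaMatrixMethod(model, params, steady_state)
    failed <- setNames(rep(FALSE, length(steady_state@fluxes)),
                       names(steady_state@fluxes))
  } else {
    mm <- .mcaFiniteDifference(model, params, steady_state, delta)
    failed <- mm$failed
    if (any(failed))
      warning(sprintf("steady-state re-solve failed for step(s) %s; coefficients flagged, theorem checks skipped there",
                      paste(names(failed)[failed], collapse = ", ")))
  }
  E <- elasticityMatrix(model, params, steady_state, method = "analytic")
  new("ControlCoefficients",
      flux_cc = mm$flux_cc, conc_cc = mm$conc_cc,
      elasticities = E,
      flags = list(failed = failed,
                   undefined = attr(E, "undefined")),
      reference = steady_state, delta = delta, method = method)
}

#' Concentration control coefficients
#'
#' Same computation as [fluxControlCoefficients()] (both matrices are
#' produced together); provided as the species-centric entry point.
#'
#' @inheritParams fluxControlCoefficients
#' @return a [ControlCoefficients-class].
#' @examples
#' f <- makeFixture("tiny_chain")
#' cc <- concentrationControlCoefficients(f$model, f$params)
#' colSums(t(cc@conc_cc))  # summation theorem: all 0
#' @export
concentrationControlCoefficients <- function(model, params,
                                             steady_state = NULL,
                                             delta = 1e-3,
                                             method = c("finite_difference",
                                                        "matrix")) {
  fluxControlCoefficients(model, params, steady_state, delta, match.arg(method))
}

#' Structured MCA report
#'
#' Ranked control-coefficient tables (largest absolute coefficient first)
#' per flux and per species, plus the summation-theorem residuals
#' (sum_i C_i^J - 1 per flux; sum_i C_i^S per species).
#'
#' @param cc a [ControlCoefficients-class].
#' @param path optional directory; when given, writes
#'   \code{flux_control.csv}, \code{concentration_control.csv} and
#'   \code{theorem_residuals.json} there.
#' @return (invisibly) a list with \code{flux_ranking},
#'   \code{conc_ranking}, \code{theorem_residuals} and
#'   \code{top_steps} (steps ranked by mean |concentration control|).
#' @export
mcaReport <- function(cc, path = NULL) {
  stopifnot(is(cc, "ControlCoefficients"))
  emptyRank <- data.frame(target = character(), step = character(),
                          coefficient = numeric())
  rank1 <- function(M) {
    if (length(M) == 0L) return(emptyRank)
    do.call(rbind, lapply(rownames(M), function(tg) {
      x <- M[tg, ]
      ord <- order(-abs(x))
      data.frame(target = tg, step = colnames(M)[ord], coefficient = x[ord],
                 row.names = NULL)
    }))
  }
  ok <- !cc@flags$failed
  fres <- if (length(cc@flux_cc)) rowSums(cc@flux_cc[, ok, drop = FALSE]) - 1 else numeric()
  cres <- if (length(cc@conc_cc)) rowSums(cc@conc_cc[, ok, drop = FALSE]) else numeric()
  top <- if (length(cc@conc_cc)) {
    ms <- colMeans(abs(cc@conc_cc), na.rm = TRUE)
    names(sort(ms, decreasing = TRUE))
  } else character()
  rep <- list(flux_ranking = rank1(cc@flux_cc),
              conc_ranking = rank1(cc@conc_cc),
              theorem_residuals = list(flux = fres, concentration = cres),
              top_steps = top)
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(cc@flux_cc),
                     file.path(path, "flux_control.csv"))
    utils::write.csv(as.data.frame(cc@conc_cc),
                     file.path(path, "concentration_control.csv"))
    jsonlite::write_json(lapply(rep$theorem_residuals, function(x)
      as.list(setNames(as.numeric(x), names(x)))),
      file.path(path, "theorem_residuals.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(rep)
}
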