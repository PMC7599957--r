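#' @import methods
#' @importFrom stats setNames
NULL

#' Reaction network of the hepatic cholesterol model
#'
#' An S4 container for a kinetic reaction network: a species table (dynamic
#' metabolites/proteins plus constant boundary pools), a list of reactions
#' with rate-law descriptors, and the pre-assembled stoichiometry matrix
#' restricted to dynamic species.
#'
#' @slot species data.frame with columns \code{id}, \code{name}, \code{role}
#'   (\code{"dynamic"} or \code{"boundary"}), \code{initial_value},
#'   \code{unit}.
#' @slot reactions list of reaction descriptors (id, name, substrates,
#'   products, reversible, rate_law, params, modifiers).
#' @slot stoich integer matrix, dynamic species x reactions; entry (s, r) is
#'   the net stoichiometric coefficient of species s in reaction r.
#'
#' @seealso [buildModel()], [stoichiometryMatrix()], [odeRHS()]
#' @export
setClass("CholModel",
  representation(
    species   = "data.frame",
    reactions = "list",
    stoich    = "matrix"
  )
)

setValidity("CholModel", function(object) {
  sp <- object@species
  msgs <- character()
  if (!all(c("id", "name", "role", "initial_value", "unit") %in% names(sp)))
    msgs <- c(msgs, "species table lacks required columns")
  if (anyDuplicated(sp$id))
    msgs <- c(msgs, sprintf("duplicated species id: %s",
                            paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  if (length(msgs) == 0L && !all(sp$role %in% c("dynamic", "boundary")))
    msgs <- c(msgs, "species role must be 'dynamic' or 'boundary'")
  if (length(msgs) == 0L && any(sp$initial_value < 0))
    msgs <- c(msgs, "negative initial_value")
  rids <- vapply(object@reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    msgs <- c(msgs, "duplicated reaction ids")
  for (r in object@reactions) {
    refs <- c(vapply(r$substrates, `[[`, character(1), "species"),
              vapply(r$products, `[[`, character(1), "species"),
              vapply(r$modifiers, `[[`, character(1), "species"))
    bad <- setdiff(refs, sp$id)
    if (length(bad))
      msgs <- c(msgs, sprintf("reaction %s references unknown species: %s",
                              r$id, paste(bad, collapse = ", ")))
  }
  ndyn <- sum(sp$role == "dynamic")
  if (length(object@reactions) > 0L &&
      !identical(dim(object@stoich), c(ndyn, length(object@reactions))))
    msgs <- c(msgs, "stoichiometry matrix dimensions inconsistent with model")
  if (length(msgs)) msgs else TRUE
})

#' Kinetic constants and initial concentrations
#'
#' Named kinetic constants with per-constant provenance tags
#' (\code{"appendix"} for values printed in the source parameterization,
#' \code{"calibrated"} for values fitted against the shipped anchor set),
#' plus the initial concentration of every species (boundary species carry
#' their constant pool value here).
#'
#' @slot constants named numeric vector of kinetic constants.
#' @slot provenance named character vector parallel to \code{constants}.
#' @slot initial named numeric vector of initial concentrations.
#'
#' @seealso [loadBaseline()], [calibrateModel()]
#' @export
setClass("ParameterSet",
  representation(
    constants  = "numeric",
    provenance = "character",
    initial    = "numeric"
  )
)

## constants that are multiplicative gains and may legitimately be zero
.zero_ok_constants <- c("ros_gain_r4")

setValidity("ParameterSet", function(object) {
  msgs <- character()
  k <- object@constants
  if (is.null(names(k)) || anyNA(names(k)) || any(names(k) == ""))
    msgs <- c(msgs, "constants must be named")
  if (any(!is.finite(k)))
    msgs <- c(msgs, "non-finite constant")
  neg <- names(k)[k < 0]
  if (length(neg))
    msgs <- c(msgs, sprintf("negative constant: %s", paste(neg, collapse = ", ")))
  zero <- setdiff(names(k)[k == 0], .zero_ok_constants)
  if (length(zero))
    msgs <- c(msgs, sprintf("constant must be positive: %s",
                            paste(zero, collapse = ", ")))
  if (!identical(sort(names(k)), sort(names(object@provenance))))
    msgs <- c(msgs, "provenance tags must cover exactly the constants")
  else if (!all(object@provenance %in% c("appendix", "calibrated")))
    msgs <- c(msgs, "provenance must be 'appendix' or 'calibrated'")
  if (any(object@initial < 0))
    msgs <- c(msgs, "negative initial concentration")
  if (length(msgs)) msgs else TRUE
})

#' Simulated time course
#'
#' @slot times numeric vector of time points (minutes), strictly increasing.
#' @slot states matrix (time x dynamic species) of concentrations.
#' @slot fluxes_at_readout numeric vector of the 30 reaction rates at the
#'   final time point.
#'
#' @seealso [simulateModel()]
#' @export
setClass("Trajectory",
  representation(
    times  = "numeric",
    states = "matrix",
    fluxes_at_readout = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(object@times) != nrow(object@states))
    msgs <- c(msgs, "times and states are inconsistent")
  if (any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Steady state with stability verdict
#'
#' @slot state named numeric steady-state concentrations (dynamic species).
#' @slot fluxes named numeric reaction rates at the steady state.
#' @slot residual_norm max-norm of the time derivatives at \code{state}.
#' @slot stable TRUE iff all Jacobian eigenvalues have negative real part.
#' @slot eigenvalues complex spectrum of the Jacobian restricted to dynamic
#'   species.
#' @slot converged whether the solver met its residual tolerance.
#' @slot method "newton", "integration+newton" or "integration".
#'
#' @seealso [findSteadyState()]
#' @export
setClass("SteadyStateResult",
  representation(
    state         = "numeric",
    fluxes        = "numeric",
    residual_norm = "numeric",
    stable        = "logical",
    eigenvalues   = "complex",
    converged     = "logical",
    method        = "character"
  )
)

#' Metabolic control analysis coefficients
#'
#' Scaled flux control coefficients \eqn{C_i^J = d\ln J / d\ln v_i},
#' concentration control coefficients \eqn{C_i^S = d\ln S / d\ln v_i} and
#' elasticities \eqn{\epsilon_{r,s} = \partial\ln v_r / \partial\ln s}, all
#' evaluated at a converged stable steady state.
#'
#' @slot flux_cc matrix (flux x perturbed step), dimensionless.
#' @slot conc_cc matrix (species x perturbed step), dimensionless.
#' @slot elasticities matrix (reaction x dynamic species), dimensionless.
#' @slot flags list of logical matrices marking entries that are undefined
#'   (zero reference flux/concentration) or failed to re-solve.
#' @slot reference the [SteadyStateResult-class] the analysis was run at.
#' @slot delta relative perturbation used by the finite-difference method.
#' @slot method "finite_difference" or "matrix".
#'
#' @seealso [fluxControlCoefficients()], [concentrationControlCoefficients()]
#' @export
setClass("ControlCoefficients",
  representation(
    flux_cc      = "matrix",
    conc_cc      = "matrix",
    elasticities = "matrix",
    flags        = "list",
    reference    = "SteadyStateResult",
    delta        = "numeric",
    method       = "character"
  )
)

#' Gridded parameter-scan result
#'
#' @slot grid data.frame, one row per grid point: the axis value(s), one
#'   column per observable, and a logical \code{ok} flag (FALSE where the
#'   integration failed).
#' @slot spec the scan specification (axes, readout time, observables).
#' @slot params_hash md5 hash of the parameter set used.
#'
#' @seealso [runScan()], [hmgcrScan()], [acat2Scan()]
#' @export
setClass("ScanResult",
  representation(
    grid        = "data.frame",
    spec        = "list",
    params_hash = "character"
  )
)

#' Result of anchor-based calibration
#'
#' @slot params fitted [ParameterSet-class].
#' @slot residuals data.frame (anchor coordinates, observable, simulated,
#'   target, relative error).
#' @slot converged logical.
#' @slot free character vector of fitted constant names.
#' @slot objective final weighted sum of squares.
#'
#' @seealso [calibrateModel()]
#' @export
setClass("CalibrationResult",
  representation(
    params    = "ParameterSet",
    residuals = "data.frame",
    converged = "logical",
    free      = "character",
    objective = "numeric"
  )
)
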