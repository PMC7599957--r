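#' Stoichiometry matrix of a model
#'
#' @param model a [CholModel-class].
#' @return integer matrix (dynamic species x reactions); boundary species are
#'   excluded. A model with no reactions yields a 0 x 0 matrix.
#' @examples
#' m <- makeFixture("tiny_chain")$model
#' stoichiometryMatrix(m)
#' @export
setGeneric("stoichiometryMatrix",
           function(model) standardGeneric("stoichiometryMatrix"))

#' @rdname stoichiometryMatrix
#' @export
setMethod("stoichiometryMatrix", "CholModel", function(model) {
  if (length(model@reactions) == 0L)
    return(matrix(0L, 0L, 0L))
  model@stoich
})

#' Species identifiers
#'
#' @param model a [CholModel-class].
#' @param role optionally restrict to \code{"dynamic"} or \code{"boundary"}.
#' @return character vector of species ids, in model order.
#' @export
speciesIds <- function(model, role = NULL) {
  stopifnot(is(model, "CholModel"))
  sp <- model@species
  if (!is.null(role)) sp <- sp[sp$role == role, , drop = FALSE]
  sp$id
}

#' Reaction identifiers
#'
#' @param model a [CholModel-class].
#' @return character vector of reaction ids, in model order.
#' @export
reactionIds <- function(model) {
  stopifnot(is(model, "CholModel"))
  vapply(model@reactions, function(r) r$id, character(1))
}

#' Kinetic constants of a parameter set
#'
#' @param params a [ParameterSet-class].
#' @return named numeric vector.
#' @export
getConstants <- function(params) {
  stopifnot(is(params, "ParameterSet"))
  params@constants
}

#' Provenance tags of a parameter set
#'
#' @param params a [ParameterSet-class].
#' @return named character vector ("appendix" or "calibrated").
#' @export
getProvenance <- function(params) {
  stopifnot(is(params, "ParameterSet"))
  params@provenance
}

#' Initial concentrations of a parameter set
#'
#' @param params a [ParameterSet-class].
#' @return named numeric vector (boundary species carry their constant value).
#' @export
initialConcentrations <- function(params) {
  stopifnot(is(params, "ParameterSet"))
  params@initial
}

#' Update constants or initial values of a parameter set
#'
#' Paths name either a kinetic constant (e.g. \code{"vmax_r4"}) or an initial
#' concentration (\code{"init.FC"}). Provenance of touched constants is left
#' unchanged; new constants are tagged "calibrated".
#'
#' @param params a [ParameterSet-class].
#' @param ... named values, or a single named vector/list.
#' @return the modified [ParameterSet-class].
#' @examples
#' p <- makeFixture("tiny_chain")$params
#' p2 <- setConstants(p, k_in = 0.2)
#' getConstants(p2)[["k_in"]]
#' @export
setConstants <- function(params, ...) {
  stopifnot(is(params, "ParameterSet"))
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && (is.list(dots[[1]]) || length(dots[[1]]) > 1L) &&
       !is.null(names(dots[[1]]))))
    dots <- as.list(dots[[1]])
  vals <- unlist(dots)
  if (is.null(names(vals)) || any(names(vals) == ""))
    stop("setConstants() requires named values")
  for (nm in names(vals)) {
    if (startsWith(nm, "init.")) {
      sp <- sub("^init\\.", "", nm)
      params@initial[[sp]] <- vals[[nm]]
    } else {
      if (!nm %in% names(params@constants))
        params@provenance[[nm]] <- "calibrated"
      params@constants[[nm]] <- vals[[nm]]
    }
  }
  validObject(params)
  params
}

#' Resolve a parameter path to its current value
#'
#' @param params a [ParameterSet-class].
#' @param path a constant name or \code{"init.<species>"}.
#' @return numeric value.
#' @export
getParam <- function(params, path) {
  stopifnot(is(params, "ParameterSet"), is.character(path))
  if (startsWith(path, "init.")) {
    sp <- sub("^init\\.", "", path)
    if (!sp %in% names(params@initial))
      stop(sprintf("unknown species in parameter path '%s'", path))
    return(params@initial[[sp]])
  }
  if (!path %in% names(params@constants))
    stop(sprintf("unknown parameter path '%s'", path))
  params@constants[[path]]
}
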