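#' Packaged model/parameter fixtures
#'
#' \describe{
#'   \item{tiny_chain}{3-species irreversible linear chain (source -> A ->
#'     B -> C -> sink) with closed-form steady state (A* = k_in/k_ab,
#'     B* = k_in/k_bc, C* = k_in/k_out), used as an analytic oracle.}
#'   \item{baseline}{the full 30-reaction hepatic model with the shipped
#'     baseline parameterization.}
#'   \item{perturbed}{baseline with a seeded multiplicative +/-10% jitter on
#'     every kinetic constant, for robustness tests; deterministic given
#'     \code{seed}.}
#' }
#'
#' @param name one of "tiny_chain", "baseline", "perturbed".
#' @param seed integer seed for the perturbed fixture.
#' @return list with elements \code{model} ([CholModel-class]) and
#'   \code{params} ([ParameterSet-class]).
#' @examples
#' f <- makeFixture("tiny_chain")
#' findSteadyState(f$model, f$params)@state
#' @export
makeFixture <- function(name = c("tiny_chain", "baseline", "perturbed"),
                        seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("tiny_chain", "baseline", "perturbed"))
    stop("unknown fixture name; valid names: tiny_chain, baseline, perturbed")
  name <- name[1]
  if (name == "tiny_chain") {
    cfg <- list(
      species = list(
        list(id = "S", role = "boundary", initial_value = 1.0),
        list(id = "A", role = "dynamic", initial_value = 0.0),
        list(id = "B", role = "dynamic", initial_value = 0.0),
        list(id = "C", role = "dynamic", initial_value = 0.0),
        list(id = "X", role = "boundary", initial_value = 0.0)),
      reactions = list(
        list(id = "Rin", substrates = list(list(species = "S")),
             products = list(list(species = "A")),
             rate_law = "mass_action_1st_order", params = list(k = "k_in")),
        list(id = "Rab", substrates = list(list(species = "A")),
             products = list(list(species = "B")),
             rate_law = "mass_action_1st_order", params = list(k = "k_ab")),
        list(id = "Rbc", substrates = list(list(species = "B")),
             products = list(list(species = "C")),
             rate_law = "mass_action_1st_order", params = list(k = "k_bc")),
        list(id = "Rout", substrates = list(list(species = "C")),
             products = list(list(species = "X")),
             rate_law = "mass_action_1st_order", params = list(k = "k_out"))))
    k <- c(k_in = 0.1, k_ab = 0.05, k_bc = 0.2, k_out = 0.08)
    params <- new("ParameterSet", constants = k,
                  provenance = setNames(rep("calibrated", length(k)), names(k)),
                  initial = c(S = 1, A = 0, B = 0, C = 0, X = 0))
    model <- buildModel(cfg, params = params)
    return(list(model = model, params = params))
  }
  model <- baselineModel()
  params <- loadBaseline()
  if (name == "perturbed") {
    set.seed(as.integer(seed))
    k <- getConstants(params)
    jitter <- stats::runif(length(k), 0.9, 1.1)
    k2 <- k * jitter
    k2[.zero_ok_constants[.zero_ok_constants %in% names(k2)]] <-
      k[.zero_ok_constants[.zero_ok_constants %in% names(k)]]
    params@constants <- k2
    validObject(params)
  }
  list(model = model, params = params)
}
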