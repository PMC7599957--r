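#' Load the baseline parameter set
#'
#' Reads a parameter YAML (defaulting to the packaged baseline), validates
#' the schema — every constant carries a value and a provenance tag
#' ("appendix" for constants printed in the source parameterization,
#' "calibrated" for constants fitted against the shipped anchors) — and
#' returns a [ParameterSet-class]. Positivity violations raise an error
#' naming the offending field.
#'
#' @param path parameter YAML path; default: the packaged baseline.
#' @return a [ParameterSet-class].
#' @examples
#' p <- loadBaseline()
#' getConstants(p)[["vmax_r4"]]  # 1.43
#' @export
loadBaseline <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "baseline_params.yaml", package = "cholsim",
                        mustWork = TRUE)
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$constants) || is.null(doc$initial))
    stop("parameter file must contain 'constants' and 'initial'")
  vals <- prov <- c()
  for (nm in names(doc$constants)) {
    entry <- doc$constants[[nm]]
    if (is.null(entry$value) || is.null(entry$provenance))
      stop(sprintf("constant '%s' lacks value/provenance", nm))
    if (!is.numeric(entry$value) || !is.finite(entry$value))
      stop(sprintf("constant '%s' has a non-numeric value", nm))
    if (entry$value < 0 || (entry$value == 0 && !nm %in% .zero_ok_constants))
      stop(sprintf("constant '%s' must be positive", nm))
    vals[nm] <- entry$value
    prov[nm] <- entry$provenance
  }
  init <- unlist(doc$initial)
  if (any(init < 0))
    stop(sprintf("negative initial concentration for '%s'",
                 names(init)[which(init < 0)[1]]))
  ps <- new("ParameterSet", constants = vals, provenance = prov, initial = init)
  validObject(ps)
  ps
}

#' The packaged anchor set
#'
#' Anchors used to calibrate (and regression-test) the baseline: the 5 x 5
#' combined-modulation grid readouts of FC, CE, LDL-C and LDLr at 3000 min,
#' plus the baseline and doubled-synthesis acetyl-CoA readouts. Columns
#' \code{vmax_r4}, \code{vmax_r15}, \code{k1} give parameter overrides (NA =
#' baseline value); LDLr anchors are down-weighted because the receptor pool
#' is carried in its own count-like unit.
#'
#' @param path anchors CSV path; default: the packaged set.
#' @return data.frame with columns vmax_r4, vmax_r15, k1, observable,
#'   target, weight.
#' @export
defaultAnchors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anchors.csv", package = "cholsim",
                        mustWork = TRUE)
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vmax_r4", "vmax_r15", "k1", "observable", "target", "weight")
  if (!all(need %in% names(a)))
    stop("anchor file lacks required columns")
  a
}

## simulate every anchor row (grouping rows sharing one override combination
## into a single integration) and return the simulated values
.simulateAnchors <- function(model, params, anchors, readout_time = 3000,
                             rtol = 1e-8, atol = 1e-10) {
  key <- paste(anchors$vmax_r4, anchors$vmax_r15, anchors$k1)
  sims <- numeric(nrow(anchors))
  for (kk in unique(key)) {
    idx <- which(key == kk)
    p <- params
    ov <- anchors[idx[1], c("vmax_r4", "vmax_r15", "k1")]
    for (nm in names(ov))
      if (!is.na(ov[[nm]])) p <- setConstants(p, setNames(ov[[nm]], nm))
    comp <- .compileModel(model, p)
    st <- .simulateReadout(comp, readout_time, rtol, atol)
    sims[idx] <- st[anchors$observable[idx]]
  }
  sims
}

#' Calibrate free constants against an anchor set
#'
#' Weighted least squares on relative residuals (weights 1/target^2 scaled
#' by the anchor \code{weight} column) using Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) on log-transformed constants, optionally with
#' multiple starts drawn log-uniformly around the incoming values. The
#' printed constants vmax_r4, vmax_r15 and k1 are pinned and may not be
#' freed. Deterministic given \code{seed}.
#'
#' @param model a [CholModel-class].
#' @param params starting [ParameterSet-class].
#' @param free character vector of constant names (or "init.<species>"
#'   paths) to fit; empty means: no fitting, just evaluate residuals.
#' @param anchors anchor data.frame (see [defaultAnchors()]).
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starts (the first is the incoming value).
#' @param spread multiplicative half-range of the log-uniform draws.
#' @param maxiter per-start Levenberg-Marquardt iteration budget.
#' @param epsfcn forward-difference step control for the internal Jacobian;
#'   keep well above the squared solver tolerance so derivative estimates
#'   are not dominated by integration noise.
#' @param readout_time anchor readout time (min).
#' @param rtol,atol solver tolerances used while fitting.
#' @return a [CalibrationResult-class]; \code{converged = FALSE} carries the
#'   best-so-far fit rather than failing.
#' @export
calibrateModel <- function(model, params, free = character(),
                           anchors = defaultAnchors(), seed = 1L,
                           n_starts = 16L, spread = 4, maxiter = 50L,
                           epsfcn = 1e-8, readout_time = 3000,
                           rtol = 1e-8, atol = 1e-10) {
  pinned <- c("vmax_r4", "vmax_r15", "k1")
  if (any(free %in% pinned))
    stop(sprintf("constants %s are pinned and cannot be calibrated",
                 paste(intersect(free, pinned), collapse = ", ")))
  for (nm in free) getParam(params, nm)  # path resolution check
  w <- sqrt(anchors$weight)

  evalResiduals <- function(p) {
    sims <- .simulateAnchors(model, p, anchors, readout_time, rtol, atol)
    list(sims = sims, res = w * (sims - anchors$target) / anchors$target)
  }

  applyFree <- function(p, logvals) {
    setConstants(p, setNames(exp(logvals), free))
  }

  if (length(free) == 0L) {
    ev <- evalResiduals(params)
    return(new("CalibrationResult", params = params,
               residuals = .residualTable(anchors, ev$sims),
               converged = TRUE, free = character(),
               objective = sum(ev$res^2)))
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  x0 <- log(vapply(free, function(nm) getParam(params, nm), numeric(1)))
  starts <- list(x0)
  if (n_starts > 1L)
    for (i in seq_len(n_starts - 1L))
      starts[[i + 1L]] <- x0 + stats::runif(length(x0), -log(spread), log(spread))

  best <- NULL
  for (x in starts) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = x,
      fn = function(lv) {
        p <- try(applyFree(params, lv), silent = TRUE)
        if (inherits(p, "try-error")) return(rep(1e3, nrow(anchors)))
        out <- try(evalResiduals(p)$res, silent = TRUE)
        if (inherits(out, "try-error")) return(rep(1e3, nrow(anchors)))
        out
      },
      control = minpack.lm::nls.lm.control(maxiter = maxiter, epsfcn = epsfcn,
                                           ftol = 1e-12, ptol = 1e-12))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("calibration failed: no start produced an evaluable fit")

  fitted <- applyFree(params, best$par)
  ev <- evalResiduals(fitted)
  new("CalibrationResult",
      params = fitted,
      residuals = .residualTable(anchors, ev$sims),
      converged = best$info %in% 1:4,
      free = free,
      objective = sum(ev$res^2))
}

.residualTable <- function(anchors, sims) {
  data.frame(anchors[, c("vmax_r4", "vmax_r15", "k1", "observable")],
             simulated = sims, target = anchors$target,
             rel_error = (sims - anchors$target) / anchors$target)
}
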