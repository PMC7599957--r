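#' Run a one- or two-dimensional parameter scan
#'
#' COPASI-style independent scan: for every grid point the named parameters
#' are set, the model is integrated from the baseline initial state to the
#' readout time, and the observables are recorded; base parameters are
#' restored between points (no state leakage, so permuting the grid order
#' leaves every cell unchanged). Grid points whose integration fails are
#' flagged (\code{ok = FALSE}) and the scan continues.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class] (the base point).
#' @param spec list with elements \code{axes} (named list: parameter path ->
#'   numeric values, 1 or 2 entries), optional \code{readout_time} (default
#'   3000 min) and \code{observables} (default FC, CE, LDLC, LDLR, HMGCoA,
#'   ACoA).
#' @param rtol,atol solver tolerances.
#' @return a [ScanResult-class]; \code{grid} has one row per grid point.
#' @examples
#' f <- makeFixture("baseline")
#' sc <- runScan(f$model, f$params,
#'               list(axes = list(vmax_r4 = c(1, 2)), readout_time = 3000))
#' sc@grid
#' @export
runScan <- function(model, params, spec, rtol = 1e-8, atol = 1e-10) {
  if (is.null(spec$axes) || !length(spec$axes) %in% 1:2)
    stop("scan spec must define 1 or 2 axes")
  readout <- if (is.null(spec$readout_time)) 3000 else spec$readout_time
  obs <- if (is.null(spec$observables))
    c("FC", "CE", "LDLC", "LDLR", "HMGCoA", "ACoA") else spec$observables
  dyn <- speciesIds(model, "dynamic")
  if (!all(obs %in% dyn))
    stop(sprintf("unknown observable(s): %s",
                 paste(setdiff(obs, dyn), collapse = ", ")))
  for (ax in names(spec$axes)) {
    vals <- spec$axes[[ax]]
    if (!all(is.finite(vals)) || any(vals <= 0))
      stop(sprintf("axis '%s' values must be finite and > 0", ax))
    getParam(params, ax)  # path must resolve
  }
  grid <- expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE)
  res <- matrix(NA_real_, nrow(grid), length(obs),
                dimnames = list(NULL, obs))
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    for (ax in names(spec$axes))
      p <- setConstants(p, setNames(grid[i, ax], ax))
    st <- try(.simulateReadout(.compileModel(model, p), readout, rtol, atol),
              silent = TRUE)
    if (inherits(st, "try-error")) {
      ok[i] <- FALSE
      next
    }
    res[i, ] <- st[obs]
  }
  out <- cbind(grid, as.data.frame(res))
  out$ok <- ok
  new("ScanResult", grid = out,
      spec = list(axes = spec$axes, readout_time = readout, observables = obs),
      params_hash = .hashParams(params))
}

#' HMG-CoA reductase activity sweep
#'
#' Sweeps Vmax of the mevalonate-formation step (the HMGCR-catalysed
#' reaction, used as a proxy for ROS-driven activation) over integer values,
#' default 1..10 uMoles/min, reading out at 3000 min.
#'
#' @param model a [CholModel-class].
#' @param params baseline [ParameterSet-class].
#' @param values Vmax values to sweep.
#' @param ... passed to [runScan()].
#' @return a [ScanResult-class].
#' @export
hmgcrScan <- function(model, params, values = 1:10, ...) {
  runScan(model, params, list(axes = list(vmax_r4 = values)), ...)
}

#' ACAT2 activity sweep
#'
#' Sweeps Vmax of the cholesterol-esterification step (ACAT2), default
#' 0.01..0.06 uMoles/min in steps of 0.01, reading out at 3000 min.
#'
#' @inheritParams hmgcrScan
#' @param values Vmax values to sweep.
#' @return a [ScanResult-class].
#' @export
acat2Scan <- function(model, params, values = seq(0.01, 0.06, by = 0.01), ...) {
  runScan(model, params, list(axes = list(vmax_r15 = values)), ...)
}

.scenarioOverrides <- function(name) {
  aging <- c(vmax_r4 = 2.86, vmax_r15 = 0.02)
  tab <- list(
    baseline        = c(),
    aging           = aging,
    high_fat        = c(k1 = 0.115),
    t2dm            = c(k1 = 0.175),
    t1dm            = c(k1 = 0.2),
    `aging+high_fat` = c(aging, k1 = 0.115),
    `aging+t2dm`    = c(aging, k1 = 0.175),
    `aging+t1dm`    = c(aging, k1 = 0.2))
  if (!name %in% names(tab))
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(names(tab), collapse = ", ")))
  tab[[name]]
}

#' Simulate a named ageing / acetyl-CoA scenario
#'
#' Applies the scenario's parameter overrides and integrates from the
#' baseline initial state to the readout time. The ageing composite doubles
#' the HMGCR Vmax to 2.86 uMoles/min and halves the ACAT2 Vmax to 0.02
#' uMoles/min; the diet/diabetes scenarios raise the acetyl-CoA synthesis
#' constant k1 from 0.1 to 0.115 (high-fat), 0.175 (T2DM) or 0.2 (T1DM).
#' Overrides combine by simultaneous assignment.
#'
#' @param model a [CholModel-class].
#' @param params baseline [ParameterSet-class].
#' @param name one of baseline, aging, high_fat, t2dm, t1dm,
#'   aging+high_fat, aging+t2dm, aging+t1dm.
#' @param readout_time minutes (default 3000).
#' @param rtol,atol solver tolerances.
#' @return one-row data.frame: scenario, readout time, ACoA, FC, CE, LDLC,
#'   LDLR.
#' @examples
#' f <- makeFixture("baseline")
#' runScenario(f$model, f$params, "baseline")$ACoA  # ~32.13
#' @export
runScenario <- function(model, params, name, readout_time = 3000,
                        rtol = 1e-8, atol = 1e-10) {
  ov <- .scenarioOverrides(name)
  p <- params
  if (length(ov)) p <- setConstants(p, ov)
  st <- .simulateReadout(.compileModel(model, p), readout_time, rtol, atol)
  data.frame(scenario = name, time = readout_time,
             ACoA = st[["ACoA"]], FC = st[["FC"]], CE = st[["CE"]],
             LDLC = st[["LDLC"]], LDLR = st[["LDLR"]],
             row.names = NULL)
}

## md5 of the canonical JSON rendering of a parameter set
.hashParams <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(list(constants = as.list(getConstants(params)),
                            initial = as.list(initialConcentrations(params))),
                       tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
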