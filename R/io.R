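## Writers for trajectories, steady states and scan grids, plus the run
## manifest.  CSVs print at 6 significant figures; a parallel JSON keeps
## full precision.

#' Write a trajectory to CSV (long format) and JSON
#'
#' @param traj a [Trajectory-class].
#' @param path output CSV path (long format: time, species, value). A
#'   \code{.json} sibling with full-precision values is written alongside.
#' @return invisibly, the paths written.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  long <- data.frame(
    time = rep(traj@times, times = ncol(traj@states)),
    species = rep(colnames(traj@states), each = length(traj@times)),
    value = as.vector(traj@states))
  out <- long
  out$value <- signif(out$value, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jpath <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(times = traj@times,
                            species = colnames(traj@states),
                            states = unname(apply(traj@states, 1, as.list)),
                            fluxes_at_readout = as.list(traj@fluxes_at_readout)),
                       jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(path, jpath))
}

#' Write a steady-state result to JSON
#'
#' @param ss a [SteadyStateResult-class].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeSteadyState <- function(ss, path) {
  stopifnot(is(ss, "SteadyStateResult"))
  jsonlite::write_json(list(
    state = as.list(ss@state),
    fluxes = as.list(ss@fluxes),
    residual_norm = ss@residual_norm,
    stable = ss@stable,
    eigenvalues = lapply(ss@eigenvalues, function(z)
      list(re = Re(z), im = Im(z))),
    converged = ss@converged,
    method = ss@method), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a scan result
#'
#' Writes the long-format grid CSV; for 2-D scans an additional wide CSV
#' per observable mirrors the printed-table layout (first axis in rows,
#' second in columns).
#'
#' @param scan a [ScanResult-class].
#' @param path output CSV path (long format). Wide companions are written
#'   as \code{<path>_<observable>_wide.csv}; a full-precision \code{.json}
#'   sibling is always written.
#' @return invisibly, the paths written.
#' @export
writeScan <- function(scan, path) {
  stopifnot(is(scan, "ScanResult"))
  g <- scan@grid
  out <- g
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  paths <- path
  axes <- names(scan@spec$axes)
  if (length(axes) == 2L) {
    for (obs in scan@spec$observables) {
      wide <- stats::reshape(g[, c(axes, obs)], timevar = axes[2],
                             idvar = axes[1], direction = "wide")
      names(wide) <- c(axes[1],
                       paste0(axes[2], "=", unique(g[[axes[2]]])))
      wide[-1] <- lapply(wide[-1], signif, digits = 6)
      wp <- sub("\\.csv$", sprintf("_%s_wide.csv", obs), path)
      utils::write.csv(wide, wp, row.names = FALSE, quote = FALSE)
      paths <- c(paths, wp)
    }
  }
  jpath <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(spec = scan@spec, grid = g,
                            params_hash = scan@params_hash),
                       jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jpath))
}

#' Write a run manifest
#'
#' Every CLI invocation records exactly one manifest: the command line, md5
#' hashes of the config and parameter set, the seed, tool version,
#' timestamps, and the list of files written.
#'
#' @param path manifest JSON path.
#' @param command character, the command line.
#' @param outputs character vector of files written.
#' @param config_path optional config file to hash.
#' @param params optional [ParameterSet-class] to hash.
#' @param seed optional integer seed.
#' @param started POSIXct start time.
#' @return invisibly, the path.
#' @export
writeManifest <- function(path, command, outputs, config_path = NULL,
                          params = NULL, seed = NULL,
                          started = Sys.time()) {
  man <- list(
    command = command,
    config_hash = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    parameter_set_hash = if (!is.null(params)) .hashParams(params) else NULL,
    seed = seed,
    tool_version = as.character(utils::packageVersion("cholsim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(man[!vapply(man, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
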