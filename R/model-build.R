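#' Build a kinetic model from a configuration document
#'
#' Reads a structured configuration (YAML/JSON file path, or an equivalent
#' nested list) describing species and reactions, validates it, and
#' assembles a [CholModel-class] with its stoichiometry matrix.
#'
#' @param config path to a YAML or JSON document, or a list with elements
#'   \code{species} and \code{reactions} (see the packaged
#'   \code{extdata/baseline_model.yaml} for the schema).
#' @param params optional [ParameterSet-class]; when supplied, every
#'   parameter reference in the config must resolve to a constant.
#' @param required_reactions optional character vector of reaction ids that
#'   must be present (e.g. \code{paste0("R", 1:30)} for the full hepatic
#'   model); a missing id raises an error naming it.
#' @return a validated [CholModel-class].
#' @examples
#' m <- baselineModel()
#' length(m@reactions)            # 30
#' sum(m@species$role == "dynamic")  # 22
#' @export
buildModel <- function(config, params = NULL, required_reactions = NULL) {
  cfg <- .readConfig(config)
  if (!is.list(cfg) || is.null(cfg$species) || is.null(cfg$reactions))
    stop("model config must contain 'species' and 'reactions'")

  sp <- do.call(rbind, lapply(cfg$species, function(s) {
    for (f in c("id", "role", "initial_value"))
      if (is.null(s[[f]])) stop(sprintf("species entry lacks field '%s'", f))
    data.frame(id = as.character(s$id),
               name = if (is.null(s$name)) as.character(s$id) else as.character(s$name),
               role = as.character(s$role),
               initial_value = as.numeric(s$initial_value),
               unit = if (is.null(s$unit)) "" else as.character(s$unit),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(sp$id))
    stop(sprintf("duplicated species id: %s",
                 paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))

  laws <- c("mass_action_1st_order", "mass_action_bimolecular",
            "michaelis_menten_irreversible", "reversible_mass_action",
            "regulated_synthesis")
  rx <- lapply(cfg$reactions, function(r) {
    for (f in c("id", "substrates", "products", "rate_law"))
      if (is.null(r[[f]])) stop(sprintf("reaction entry lacks field '%s'", f))
    if (!r$rate_law %in% laws)
      stop(sprintf("reaction %s: unknown rate law '%s'", r$id, r$rate_law))
    list(id = as.character(r$id),
         name = if (is.null(r$name)) as.character(r$id) else as.character(r$name),
         substrates = lapply(r$substrates, function(x)
           list(species = as.character(x$species),
                coef = if (is.null(x$coef)) 1 else as.numeric(x$coef))),
         products = lapply(r$products, function(x)
           list(species = as.character(x$species),
                coef = if (is.null(x$coef)) 1 else as.numeric(x$coef))),
         reversible = isTRUE(r$reversible),
         rate_law = r$rate_law,
         params = lapply(r$params, as.character),
         modifiers = if (is.null(r$modifiers)) list() else
           lapply(r$modifiers, function(m)
             list(species = as.character(m$species),
                  mode = as.character(m$mode),
                  gain = if (is.null(m$gain)) NA_character_ else as.character(m$gain),
                  ki = if (is.null(m$ki)) NA_character_ else as.character(m$ki),
                  lumped = isTRUE(m$lumped))))
  })

  rids <- vapply(rx, `[[`, character(1), "id")
  if (!is.null(required_reactions)) {
    missing <- setdiff(required_reactions, rids)
    if (length(missing))
      stop(sprintf("model config is missing required reaction(s): %s",
                   paste(missing, collapse = ", ")))
  }

  model <- new("CholModel", species = sp, reactions = rx,
               stoich = .assembleStoich(sp, rx))
  validObject(model)
  if (!is.null(params))
    .checkParamBindings(model, params)
  model
}

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    if (grepl("\\.json$", config, ignore.case = TRUE))
      return(jsonlite::read_json(config))
    return(yaml::read_yaml(config))
  }
  config
}

.assembleStoich <- function(sp, rx) {
  dyn <- sp$id[sp$role == "dynamic"]
  N <- matrix(0, length(dyn), length(rx),
              dimnames = list(dyn, vapply(rx, `[[`, character(1), "id")))
  for (j in seq_along(rx)) {
    for (s in rx[[j]]$substrates)
      if (s$species %in% dyn) N[s$species, j] <- N[s$species, j] - s$coef
    for (p in rx[[j]]$products)
      if (p$species %in% dyn) N[p$species, j] <- N[p$species, j] + p$coef
  }
  N
}

.checkParamBindings <- function(model, params) {
  k <- getConstants(params)
  for (r in model@reactions) {
    refs <- unlist(r$params, use.names = FALSE)
    for (m in r$modifiers) refs <- c(refs, m$gain, m$ki)
    refs <- refs[!is.na(refs)]
    bad <- setdiff(refs, names(k))
    if (length(bad))
      stop(sprintf("reaction %s references missing parameter(s): %s",
                   r$id, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' The packaged baseline hepatic cholesterol model
#'
#' Loads the shipped 30-reaction network (mevalonate-arm biosynthesis,
#' FC/CE interconversion, LDL-C turnover with SREBP-2-regulated receptor
#' synthesis, ROS/antioxidant subsystem and enzyme turnover).
#'
#' @return a [CholModel-class] with 30 reactions and 22 dynamic species.
#' @export
baselineModel <- function() {
  path <- system.file("extdata", "baseline_model.yaml", package = "cholsim",
                      mustWork = TRUE)
  buildModel(path, required_reactions = paste0("R", 1:30))
}
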