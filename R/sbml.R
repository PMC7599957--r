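## SBML Level 3 Version 2 export/import.  Kinetic laws are emitted as
## MathML for interoperability; in addition a model-level annotation carries
## the package's own config/parameter document (JSON), which the importer
## reads back for a lossless round trip.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.CHOLSIM_NS <- "https://cholsim.invalid/sbml/annotation"

.mlCi <- function(x) sprintf("<ci> %s </ci>", x)
.mlCn <- function(x) sprintf("<cn> %.17g </cn>", x)
.mlApply <- function(op, ...) sprintf("<apply><%s/>%s</apply>", op,
                                      paste0(..., collapse = ""))

## MathML for one reaction's rate law (parameter names as <ci>)
.kineticMathML <- function(r) {
  subs <- vapply(r$substrates, `[[`, character(1), "species")
  law <- r$rate_law
  core <- switch(law,
    mass_action_1st_order = .mlApply("times", .mlCi(r$params$k), .mlCi(subs[1])),
    mass_action_bimolecular = .mlApply("times", .mlCi(r$params$k),
                                       .mlCi(subs[1]), .mlCi(subs[2])),
    michaelis_menten_irreversible = .mlApply("divide",
      .mlApply("times", .mlCi(r$params$vmax), .mlCi(subs[1])),
      .mlApply("plus", .mlCi(r$params$km), .mlCi(subs[1]))),
    reversible_mass_action = {
      prods <- vapply(r$products, `[[`, character(1), "species")
      .mlApply("minus",
               .mlApply("times", .mlCi(r$params$kf), .mlCi(subs[1])),
               .mlApply("times", .mlCi(r$params$kr), .mlCi(prods[1])))
    },
    regulated_synthesis = {
      acts <- Filter(function(m) m$mode == "activator", r$modifiers)
      terms <- c(.mlCi(r$params$basal),
                 vapply(acts, function(m)
                   .mlApply("times", .mlCi(m$gain), .mlCi(m$species)),
                   character(1)))
      .mlApply("times", .mlCi(subs[1]),
               if (length(terms) > 1) .mlApply("plus", paste0(terms, collapse = ""))
               else terms)
    },
    stop("unknown rate law"))
  for (m in r$modifiers) {
    if (m$mode == "catalyst" && !m$lumped)
      core <- .mlApply("times", core, .mlCi(m$species))
    if (m$mode == "activator" && law != "regulated_synthesis")
      core <- .mlApply("times", core,
                       .mlApply("plus", .mlCn(1),
                                .mlApply("times", .mlCi(m$gain), .mlCi(m$species))))
    if (m$mode == "inhibitor")
      core <- .mlApply("times", core,
                       .mlApply("divide", .mlCi(m$ki),
                                .mlApply("plus", .mlCi(m$ki), .mlCi(m$species))))
  }
  sprintf("<math xmlns=\"%s\">%s</math>", .MATHML_NS, core)
}

## reconstruct the config-list rendering of a model (for the annotation)
.modelToConfig <- function(model) {
  list(
    species = lapply(seq_len(nrow(model@species)), function(i) {
      s <- model@species[i, ]
      list(id = s$id, name = s$name, role = s$role,
           initial_value = s$initial_value, unit = s$unit)
    }),
    reactions = lapply(model@reactions, function(r) {
      out <- list(id = r$id, name = r$name,
                  substrates = lapply(r$substrates, function(x)
                    list(species = x$species, coef = x$coef)),
                  products = lapply(r$products, function(x)
                    list(species = x$species, coef = x$coef)),
                  reversible = r$reversible,
                  rate_law = r$rate_law,
                  params = r$params)
      if (length(r$modifiers))
        out$modifiers <- lapply(r$modifiers, function(m) {
          mm <- list(species = m$species, mode = m$mode)
          if (!is.na(m$gain)) mm$gain <- m$gain
          if (!is.na(m$ki)) mm$ki <- m$ki
          if (m$lumped) mm$lumped <- TRUE
          mm
        })
      out
    }))
}

#' Export the model as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document: one compartment, every
#' species (boundary pools flagged \code{boundaryCondition="true"} and
#' \code{constant="true"}), every kinetic constant as a global parameter,
#' and all reactions with their kinetic laws as MathML. A model-level
#' annotation embeds the package's own config and parameter documents so
#' [importSBML()] can reconstruct the exact model.
#'
#' @param model a [CholModel-class].
#' @param params a [ParameterSet-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportSBML <- function(model, params, path) {
  stopifnot(is(model, "CholModel"), is(params, "ParameterSet"))
  k <- getConstants(params)
  init <- initialConcentrations(params)
  sp <- model@species
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  buf <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", .SBML_NS),
    "<model id=\"hepatic_cholesterol_homeostasis\" name=\"Hepatic intracellular cholesterol homeostasis\">",
    "<annotation>",
    sprintf("<cholsim:document xmlns:cholsim=\"%s\">", .CHOLSIM_NS),
    sprintf("<cholsim:config><![CDATA[%s]]></cholsim:config>",
            jsonlite::toJSON(.modelToConfig(model), auto_unbox = TRUE, digits = NA)),
    sprintf("<cholsim:parameters><![CDATA[%s]]></cholsim:parameters>",
            jsonlite::toJSON(list(constants = as.list(k),
                                  provenance = as.list(getProvenance(params)),
                                  initial = as.list(init)),
                             auto_unbox = TRUE, digits = NA)),
    "</cholsim:document>",
    "</annotation>",
    "<listOfCompartments>",
    "<compartment id=\"liver\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>")
  if (nrow(sp) > 0) {
    buf <- c(buf, "<listOfSpecies>")
    for (i in seq_len(nrow(sp))) {
      bnd <- sp$role[i] == "boundary"
      v <- if (sp$id[i] %in% names(init)) init[[sp$id[i]]] else sp$initial_value[i]
      buf <- c(buf, sprintf(
        "<species id=\"%s\" name=\"%s\" compartment=\"liver\" initialConcentration=\"%.17g\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"%s\" constant=\"%s\"/>",
        sp$id[i], esc(sp$name[i]), v, tolower(bnd), tolower(bnd)))
    }
    buf <- c(buf, "</listOfSpecies>")
  }
  if (length(k) > 0) {
    buf <- c(buf, "<listOfParameters>")
    for (nm in names(k))
      buf <- c(buf, sprintf("<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
                            nm, k[[nm]]))
    buf <- c(buf, "</listOfParameters>")
  }
  if (length(model@reactions) > 0) {
    buf <- c(buf, "<listOfReactions>")
    for (r in model@reactions) {
      buf <- c(buf, sprintf("<reaction id=\"%s\" name=\"%s\" reversible=\"%s\">",
                            r$id, esc(r$name), tolower(r$reversible)))
      buf <- c(buf, "<listOfReactants>")
      for (s in r$substrates)
        buf <- c(buf, sprintf("<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
                              s$species, s$coef))
      buf <- c(buf, "</listOfReactants>")
      buf <- c(buf, "<listOfProducts>")
      for (s in r$products)
        buf <- c(buf, sprintf("<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
                              s$species, s$coef))
      buf <- c(buf, "</listOfProducts>")
      if (length(r$modifiers)) {
        buf <- c(buf, "<listOfModifiers>")
        for (m in r$modifiers)
          buf <- c(buf, sprintf("<modifierSpeciesReference species=\"%s\"/>",
                                m$species))
        buf <- c(buf, "</listOfModifiers>")
      }
      buf <- c(buf, "<kineticLaw>", .kineticMathML(r), "</kineticLaw>",
               "</reaction>")
    }
    buf <- c(buf, "</listOfReactions>")
  }
  buf <- c(buf, "</model>", "</sbml>")
  ## parse before writing: guarantees the document is well-formed XML
  doc <- xml2::read_xml(paste0(buf, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model exported by [exportSBML()]
#'
#' Reads the embedded config/parameter annotation and reconstructs the
#' model and parameter set exactly. Documents from other tools are not
#' supported (general MathML is not parsed).
#'
#' @param path SBML file path.
#' @return list with elements \code{model} and \code{params}.
#' @export
importSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(c_ = .CHOLSIM_NS)
  cfgNode <- xml2::xml_find_first(doc, ".//c_:config", ns)
  parNode <- xml2::xml_find_first(doc, ".//c_:parameters", ns)
  if (inherits(cfgNode, "xml_missing") || inherits(parNode, "xml_missing"))
    stop("document lacks the cholsim annotation; only SBML written by exportSBML() can be imported")
  cfg <- jsonlite::fromJSON(xml2::xml_text(cfgNode), simplifyVector = FALSE)
  pj <- jsonlite::fromJSON(xml2::xml_text(parNode), simplifyVector = FALSE)
  params <- new("ParameterSet",
                constants = unlist(pj$constants),
                provenance = unlist(pj$provenance),
                initial = unlist(pj$initial))
  validObject(params)
  model <- buildModel(cfg, params = params)
  list(model = model, params = params)
}
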