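SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML-legal identifiers: raw metabolite strings are legal SId characters
# already, but ids are prefixed (M_, R_) and internal reactions keyed by
# (product, split position) because "+" and "->" are not. The original id is
# kept in the name attribute.
sbml_species_id <- function(met) paste0("M_", met)
sbml_reaction_id <- function(id, type, product = NULL, split_pos = NULL) {
  switch(type,
         internal = paste0("R_", product, "_", split_pos),
         import = paste0("R_", id),
         export = paste0("R_", id),
         biomass = "R_BIOMASS")
}

#' Export a model (or universe) as SBML Level 3 with flux bounds
#'
#' Writes SBML L3V1 with the fbc version 2 extension: species for every
#' metabolite, reactions with stoichiometry and flux bounds, and (for models)
#' the biomass maximization objective. A bare universe exports its internal
#' reactions with default reversible bounds and no objective. Species ids are
#' prefixed `M_`, reactions `R_`; original string ids live in the `name`
#' attributes.
#'
#' @param x A [build_model()] model, a `pruned_network` (its rebuilt model is
#'   exported) or a [chem_universe()].
#' @param path Output file path.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(x, path, model_id = "string_chemistry") {
  if (inherits(x, "pruned_network")) x <- rebuild_model(x)
  if (inherits(x, "chem_universe")) {
    universe <- x
    rxn_univ <- enumerate_reactions(universe)
    b <- model_bounds()
    rxn <- tibble(id = rxn_univ$id, type = "internal",
                  lb = b$internal[1], ub = b$internal[2], obj = 0)
    S <- build_stoichiometric_matrix(universe)
    mets <- rownames(S)
    objective <- character()
  } else if (inherits(x, "network_model")) {
    rxn <- x$reactions
    rxn_univ <- enumerate_reactions(x$universe)
    S <- x$S
    mets <- x$metabolites
    objective <- "R_BIOMASS"
  } else {
    stop("expected a chem_universe, network_model or pruned_network",
         call. = FALSE)
  }
  univ_lookup <- setNames(seq_len(nrow(rxn_univ)), rxn_univ$id)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, `xmlns:fbc` = SBML_FBC_NS,
    level = "3", version = "1", `fbc:required` = "false")
  model <- xml2::xml_add_child(doc, "model", id = model_id,
                               `fbc:strict` = "false")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in mets) {
    xml2::xml_add_child(species, "species", id = sbml_species_id(m), name = m,
                        compartment = "c", hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  bkey <- function(v) sprintf("%.15g", v)
  bound_vals <- sort(unique(c(rxn$lb, rxn$ub)))
  bound_ids <- setNames(paste0("bnd_", seq_along(bound_vals)),
                        vapply(bound_vals, bkey, character(1)))
  params <- xml2::xml_add_child(model, "listOfParameters")
  for (k in seq_along(bound_vals)) {
    xml2::xml_add_child(params, "parameter", id = bound_ids[[k]],
                        value = bkey(bound_vals[k]),
                        constant = "true", sboTerm = "SBO:0000626")
  }
  bound_id <- function(v) bound_ids[[bkey(v)]]

  rxns_node <- xml2::xml_add_child(model, "listOfReactions")
  Tsp <- methods::as(S, "TsparseMatrix")
  coef_by_col <- split(data.frame(i = Tsp@i + 1L, x = Tsp@x), Tsp@j + 1L)
  for (k in seq_len(nrow(rxn))) {
    type <- rxn$type[k]
    u <- univ_lookup[rxn$id[k]]
    sid <- if (type == "internal") {
      sbml_reaction_id(rxn$id[k], type, rxn_univ$product[u], rxn_univ$split_pos[u])
    } else sbml_reaction_id(rxn$id[k], type)
    node <- xml2::xml_add_child(
      rxns_node, "reaction", id = sid, name = rxn$id[k],
      reversible = if (rxn$lb[k] < 0) "true" else "false", fast = "false",
      `fbc:lowerFluxBound` = bound_id(rxn$lb[k]),
      `fbc:upperFluxBound` = bound_id(rxn$ub[k]))
    cf <- coef_by_col[[as.character(k)]]
    reactants <- cf[cf$x < 0, , drop = FALSE]
    products <- cf[cf$x > 0, , drop = FALSE]
    if (nrow(reactants)) {
      ln <- xml2::xml_add_child(node, "listOfReactants")
      for (r in seq_len(nrow(reactants))) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_species_id(mets[reactants$i[r]]),
                            stoichiometry = format(-reactants$x[r], digits = 15),
                            constant = "true")
      }
    }
    if (nrow(products)) {
      ln <- xml2::xml_add_child(node, "listOfProducts")
      for (r in seq_len(nrow(products))) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_species_id(mets[products$i[r]]),
                            stoichiometry = format(products$x[r], digits = 15),
                            constant = "true")
      }
    }
  }

  if (length(objective)) {
    objs <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                                `fbc:activeObjective` = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", `fbc:id` = "obj",
                              `fbc:type` = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (o in objective) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective", `fbc:reaction` = o,
                          `fbc:coefficient` = "1")
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
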