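#' Write all artifacts of a chemical universe to a directory
#'
#' Writes the metabolite list (`metabolites.tsv`), reaction list
#' (`reactions.tsv`), dense stoichiometric matrix (`stoich_matrix.csv`),
#' sparse triplets (`stoich_triplets.tsv`) and an SBML model
#' (`universe.sbml`). Refuses universes with more than `max_reactions`
#' reactions unless `force = TRUE` — sizes grow explosively with `A` and `L`.
#'
#' @param universe A [chem_universe()].
#' @param dir Output directory (created if missing).
#' @param force Override the size guard.
#' @param max_reactions Size guard threshold (default 1e6 reactions).
#' @return The directory, invisibly.
#' @export
write_universe <- function(universe, dir, force = FALSE, max_reactions = 1e6) {
  stopifnot(inherits(universe, "chem_universe"))
  n_rxn <- count_reactions(universe$n_monomers, universe$max_len)
  if (n_rxn > max_reactions && !force) {
    stop(sprintf(
      "universe has %.3g reactions (> %.3g); pass force = TRUE to proceed",
      n_rxn, max_reactions), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(enumerate_metabolites(universe),
                     file.path(dir, "metabolites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(enumerate_reactions(universe),
                     file.path(dir, "reactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  S <- build_stoichiometric_matrix(universe)
  write_stoich_csv(S, file.path(dir, "stoich_matrix.csv"))
  write_stoich_triplets(S, file.path(dir, "stoich_triplets.tsv"))
  write_sbml(universe, file.path(dir, "universe.sbml"))
  invisible(dir)
}

pruned_to_list <- function(pruned) {
  list(
    universe = list(alphabet = pruned$universe$alphabet,
                    max_len = pruned$universe$max_len),
    algorithm = pruned$algorithm,
    nutrients = pruned$nutrients,
    biomass = as.list(pruned$biomass),
    allow_export = pruned$allow_export,
    retained = pruned$retained,
    inclusion = pruned$inclusion,
    biomass_flux = pruned$biomass_flux,
    trajectory = pruned$trajectory,
    bounds = pruned$bounds)
}

#' Serialize a pruned network to JSON (and back)
#'
#' The JSON records everything needed to rebuild the pruned model from
#' scratch: universe parameters, nutrients, biomass coefficients, export
#' flag, retained reaction ids, the 0/1 inclusion vector over the universe
#' enumeration, the optimal biomass flux and the pruning trajectory.
#'
#' @param pruned A `pruned_network`.
#' @param path File path.
#' @return `path` (writer) or a `pruned_network` (reader).
#' @export
write_pruned_json <- function(pruned, path) {
  stopifnot(inherits(pruned, "pruned_network"))
  jsonlite::write_json(pruned_to_list(pruned), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pruned_json
#' @export
read_pruned_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  universe <- chem_universe(alphabet = x$universe$alphabet,
                            max_len = x$universe$max_len)
  structure(
    list(universe = universe, retained = as.character(x$retained),
         inclusion = as.integer(x$inclusion),
         biomass_flux = as.numeric(x$biomass_flux),
         trajectory = as.integer(x$trajectory),
         algorithm = x$algorithm,
         nutrients = as.character(x$nutrients),
         biomass = unlist(x$biomass),
         allow_export = isTRUE(x$allow_export),
         bounds = lapply(x$bounds, as.numeric)),
    class = "pruned_network")
}

#' Write ensemble records to disk
#'
#' Writes `records.jsonl` (one JSON object per record), `inclusion.csv` (one
#' row per feasible record, one 0/1 column per universe reaction id, keyed by
#' `biomass_set_id`/`nutrient_set_id`) and `records.csv` (the scalar columns).
#'
#' @param records A [run_ensemble()] tibble.
#' @param universe The [chem_universe()] the records were generated from
#'   (provides reaction ids for the CSV header).
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_ensemble <- function(records, universe, dir) {
  stopifnot(inherits(universe, "chem_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- dplyr::select(records, -dplyr::any_of(c("inclusion", "trajectory")))
  write.csv(scalars, file.path(dir, "records.csv"), row.names = FALSE)

  con <- file(file.path(dir, "records.jsonl"), "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    row <- as.list(scalars[k, ])
    row$inclusion <- records$inclusion[[k]]
    row$trajectory <- records$trajectory[[k]]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }

  feas <- records[records$feasible, ]
  inc <- do.call(rbind, feas$inclusion)
  colnames(inc) <- enumerate_reactions(universe)$id
  inc_df <- cbind(feas[, c("biomass_set_id", "nutrient_set_id")],
                  as.data.frame(inc, check.names = FALSE))
  write.csv(inc_df, file.path(dir, "inclusion.csv"), row.names = FALSE)
  invisible(dir)
}
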