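#' Default flux bounds for string-chemistry models
#'
#' Box constraints used when assembling a model: internal condensation/
#' splitting reactions are fully reversible, exchanges and biomass are
#' irreversible in their defined direction. All results reported as ratios or
#' zero/nonzero patterns are invariant to these conventional magnitudes; only
#' absolute optimal fluxes depend on them.
#'
#' @param internal,import,export,biomass Length-2 numeric `(lower, upper)`.
#' @return A named list of bounds.
#' @export
model_bounds <- function(internal = c(-1000, 1000),
                         import = c(0, 100),
                         export = c(0, 1000),
                         biomass = c(0, 1000)) {
  list(internal = internal, import = import, export = export, biomass = biomass)
}

#' Assemble a constraint-based model on a string-chemistry network
#'
#' Adds to the universe's internal reactions: one import exchange per
#' nutrient, one export exchange per metabolite when `allow_export = TRUE`
#' (none otherwise, so the biomass reaction is the only sink), and a single
#' irreversible biomass reaction jointly consuming all precursors. The
#' objective selects the biomass reaction.
#'
#' @param universe A [chem_universe()].
#' @param nutrients Character vector of metabolite ids that can be imported.
#' @param biomass Biomass precursors: either a character vector (all
#'   stoichiometric coefficients 1) or a named positive numeric vector of
#'   coefficients.
#' @param allow_export Add export exchanges for every metabolite (`TRUE`,
#'   default) or for none (`FALSE`).
#' @param reactions Optional subset of internal reaction ids (default: the
#'   whole universe).
#' @param bounds A [model_bounds()] list.
#' @return An object of class `network_model`.
#' @examples
#' u <- chem_universe(2, 3)
#' m <- build_model(u, nutrients = "ab", biomass = c(aab = 1))
#' solve_fba(m)
#' @export
build_model <- function(universe, nutrients, biomass, allow_export = TRUE,
                        reactions = NULL, bounds = model_bounds()) {
  stopifnot(inherits(universe, "chem_universe"))
  mets <- enumerate_metabolites(universe)$id
  if (is.character(biomass)) biomass <- setNames(rep(1, length(biomass)), biomass)
  if (length(biomass) == 0L) stop("`biomass` must name at least one precursor",
                                  call. = FALSE)
  if (is.null(names(biomass)) || any(!nzchar(names(biomass))) ||
      any(biomass <= 0)) {
    stop("`biomass` must be a named vector of positive coefficients",
         call. = FALSE)
  }
  nutrients <- unique(as.character(nutrients))
  for (set in list(nutrients, names(biomass))) {
    bad <- setdiff(set, mets)
    if (length(bad)) {
      stop("metabolite id(s) not in universe: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  rxn_univ <- enumerate_reactions(universe)
  if (is.null(reactions)) {
    internal <- rxn_univ
  } else {
    bad <- setdiff(reactions, rxn_univ$id)
    if (length(bad)) stop("unknown reaction id(s): ",
                          paste(head(bad, 5), collapse = ", "), call. = FALSE)
    internal <- rxn_univ[rxn_univ$id %in% reactions, ]
  }
  S_int <- build_stoichiometric_matrix(universe, reactions = internal$id)

  met_idx <- setNames(seq_along(mets), mets)
  exports <- if (allow_export) mets else character()
  block <- function(ids, prefix, type, b, obj) {
    if (length(ids) == 0L) return(NULL)
    tibble(id = paste0(prefix, ids), type = type,
           lb = rep(b[1], length(ids)), ub = rep(b[2], length(ids)), obj = obj)
  }
  rxn <- dplyr::bind_rows(
    block(internal$id, "", "internal", bounds$internal, 0),
    block(nutrients, "IMP_", "import", bounds$import, 0),
    block(exports, "EXP_", "export", bounds$export, 0),
    block("BIOMASS", "", "biomass", bounds$biomass, 1))

  n_imp <- length(nutrients); n_exp <- length(exports); n_bm <- length(biomass)
  extra <- Matrix::sparseMatrix(
    i = c(met_idx[nutrients], met_idx[exports], met_idx[names(biomass)]),
    j = c(seq_len(n_imp), n_imp + seq_len(n_exp), rep(n_imp + n_exp + 1L, n_bm)),
    x = c(rep(1, n_imp), rep(-1, n_exp), -unname(biomass)),
    dims = c(length(mets), n_imp + n_exp + 1L))
  S <- cbind(S_int, extra)
  dimnames(S) <- list(mets, rxn$id)

  structure(
    list(universe = universe, metabolites = mets, reactions = rxn, S = S,
         nutrients = nutrients, biomass = biomass,
         allow_export = allow_export, bounds = bounds),
    class = "network_model")
}

#' @export
#' @method print network_model
print.network_model <- function(x, ...) {
  tab <- table(factor(x$reactions$type,
                      levels = c("internal", "import", "export", "biomass")))
  cat(sprintf(
    "<network_model> A = %d, L = %d | %d internal, %d import, %d export, %d biomass\n",
    x$universe$n_monomers, x$universe$max_len,
    tab[["internal"]], tab[["import"]], tab[["export"]], tab[["biomass"]]))
  cat(sprintf("  nutrients: %s | precursors: %s | export %s\n",
              paste(x$nutrients, collapse = ", "),
              paste(names(x$biomass), collapse = ", "),
              if (x$allow_export) "allowed" else "forbidden"))
  invisible(x)
}

# Solve max obj'v s.t. Sv = 0, lb <= v <= ub on a prebuilt dense matrix.
# Returns list(fluxes, objective_value, status, residual, iterations).
lp_solve <- function(S_dense, lb, ub, obj, rxn_ids) {
  res <- simplex_box_lp(obj, S_dense, lb, ub, tol = .LP_TOL)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "unbounded", "failed")
  v <- setNames(as.numeric(res$x), rxn_ids)
  residual <- if (length(v)) max(abs(S_dense %*% v)) else 0
  list(fluxes = v, objective_value = res$objective, status = status,
       residual = residual, iterations = res$iterations)
}

#' Solve the flux balance linear program of a model
#'
#' Maximizes the objective (by default the biomass flux) over all steady-state
#' flux vectors: `max c'v` subject to `S v = 0` and the model's box bounds.
#' The returned flux vector is one optimal vertex; with degenerate optima the
#' objective value is unique but the vertex need not be.
#'
#' @param model A [build_model()] object.
#' @return An object of class `flux_solution` with fields `fluxes` (named
#'   vector), `objective_value`, `status` (`"optimal"`, `"unbounded"` or
#'   `"failed"`), and `residual` (max steady-state violation, `max |S v|`).
#' @export
solve_fba <- function(model) {
  stopifnot(inherits(model, "network_model"))
  sol <- lp_solve(as.matrix(model$S), model$reactions$lb, model$reactions$ub,
                  model$reactions$obj, model$reactions$id)
  if (sol$status == "failed") {
    stop("LP solver failed (iteration limit); model reported, not silently zero",
         call. = FALSE)
  }
  structure(c(sol, list(reaction_types = setNames(model$reactions$type,
                                                  model$reactions$id))),
            class = "flux_solution")
}

#' @export
#' @method print flux_solution
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s | objective: %.6g | max |Sv|: %.2e\n",
              x$status, x$objective_value, x$residual))
  nz <- sum(abs(x$fluxes) > .ZERO_FLUX_TOL)
  cat(sprintf("  %d of %d reactions carry flux\n", nz, length(x$fluxes)))
  invisible(x)
}

#' @describeIn solve_fba One row per reaction: `reaction`, `type`, `flux`.
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble(reaction = names(x$fluxes),
         type = unname(x$reaction_types[names(x$fluxes)]),
         flux = unname(x$fluxes))
}

#' @describeIn solve_fba One-row summary: objective, status, residual, number
#'   of active reactions.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(objective_value = x$objective_value, status = x$status,
         residual = x$residual,
         n_active = sum(abs(x$fluxes) > .ZERO_FLUX_TOL))
}

#' Objective impact of every single reaction deletion
#'
#' For each candidate internal reaction, the optimal biomass objective of the
#' model with that one reaction's bounds fixed to zero. Deleting a reaction
#' that carries no flux in the supplied optimum cannot change the optimum (the
#' current solution stays feasible and no deletion can improve it), so those
#' impacts are filled in without re-solving; every other candidate is
#' re-solved from scratch.
#'
#' @param model A [build_model()] object.
#' @param solution Optional [solve_fba()] result for `model`; when `NULL` it
#'   is computed (and the zero-flux shortcut still applies).
#' @param reactions Candidate reaction ids (default: all internal reactions).
#' @return A tibble with columns `reaction` and `objective_value`.
#' @export
single_deletion_impacts <- function(model, solution = NULL, reactions = NULL) {
  stopifnot(inherits(model, "network_model"))
  if (is.null(solution)) solution <- solve_fba(model)
  if (is.null(reactions)) {
    reactions <- model$reactions$id[model$reactions$type == "internal"]
  }
  S_dense <- as.matrix(model$S)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  obj <- model$reactions$obj; ids <- model$reactions$id
  out <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], ids)
    if (is.na(j)) stop("unknown reaction id: ", reactions[k], call. = FALSE)
    if (abs(solution$fluxes[[j]]) < .ZERO_FLUX_TOL) {
      out[k] <- solution$objective_value
    } else {
      lb2 <- lb; ub2 <- ub; lb2[j] <- 0; ub2[j] <- 0
      out[k] <- lp_solve(S_dense, lb2, ub2, obj, ids)$objective_value
    }
  }
  tibble(reaction = reactions, objective_value = out)
}
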