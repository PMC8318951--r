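# Internal scratch representation used by the pruning loops: the model's
# dense matrix and bound/objective vectors, solved repeatedly on column
# subsets. Columns are addressed by index into the model's reaction table.
prune_state <- function(model) {
  list(S = as.matrix(model$S),
       lb = model$reactions$lb, ub = model$reactions$ub,
       obj = model$reactions$obj, ids = model$reactions$id,
       internal = which(model$reactions$type == "internal"),
       fixed = which(model$reactions$type != "internal"))
}

solve_subset <- function(st, active_internal) {
  cols <- c(active_internal, st$fixed)
  lp_solve(st$S[, cols, drop = FALSE], st$lb[cols], st$ub[cols],
           st$obj[cols], st$ids[cols])
}

new_pruned_network <- function(model, active_internal, st, biomass_flux,
                               trajectory, algorithm, n_solves,
                               restored = NULL) {
  retained <- st$ids[active_internal]
  univ_rxn <- enumerate_reactions(model$universe)$id
  inclusion <- as.integer(univ_rxn %in% retained)
  structure(
    list(universe = model$universe, retained = retained,
         inclusion = inclusion, biomass_flux = biomass_flux,
         trajectory = trajectory, algorithm = algorithm,
         nutrients = model$nutrients, biomass = model$biomass,
         allow_export = model$allow_export, bounds = model$bounds,
         n_solves = n_solves, restored = restored),
    class = "pruned_network")
}

#' Prune a network to a minimal subnetwork by the minimum-flux rule
#'
#' Iteratively reduces the model's internal reactions while keeping biomass
#' production feasible. Each iteration solves FBA, removes every internal
#' reaction carrying no flux, and additionally removes the internal reaction
#' with the smallest nonzero absolute flux (ties broken by enumeration
#' order). When that last removal drives the biomass objective to zero, the
#' reaction is put back and pruning stops. The result is a greedy local
#' minimum: the restored reaction is provably irremovable, but the network is
#' not guaranteed to be globally smallest.
#'
#' @param model A [build_model()] object whose full network supports a
#'   positive biomass flux (otherwise an error is raised before any pruning).
#' @return An object of class `pruned_network` with fields `retained`
#'   (internal reaction ids kept), `inclusion` (0/1 vector over the
#'   universe's reaction enumeration), `biomass_flux` (> 0), `trajectory`
#'   (internal reaction count after each iteration, strictly decreasing) and
#'   `restored` (the reaction put back at termination, when one was).
#' @examples
#' u <- chem_universe(1, 2)
#' m <- build_model(u, nutrients = "a", biomass = "aa")
#' prune_min_flux(m)$retained  # "a+a->aa"
#' @export
prune_min_flux <- function(model) {
  stopifnot(inherits(model, "network_model"))
  st <- prune_state(model)
  active <- st$internal
  sol <- solve_subset(st, active)
  n_solves <- 1L
  if (sol$objective_value < .ZERO_FLUX_TOL) {
    stop("full model has zero biomass flux; nothing to prune", call. = FALSE)
  }
  trajectory <- length(active)
  restored <- NULL
  repeat {
    v <- sol$fluxes[seq_along(active)]
    zero <- abs(v) < .ZERO_FLUX_TOL
    if (all(zero)) {            # biomass fed by exchanges alone
      active <- active[!zero]
      trajectory <- c(trajectory, length(active))
      break
    }
    nz <- which(!zero)
    smallest <- nz[which.min(abs(v[nz]))]   # which.min: earliest on ties
    keep <- active[!zero & seq_along(active) != smallest]
    trial <- solve_subset(st, keep)
    n_solves <- n_solves + 1L
    if (trial$objective_value < .ZERO_FLUX_TOL) {
      # restore the last-deleted reaction; zero-flux removals are always safe
      restored <- st$ids[active[smallest]]
      active <- active[!zero]
      trajectory <- c(trajectory, length(active))
      break
    }
    active <- keep
    sol <- trial
    trajectory <- c(trajectory, length(active))
  }
  trajectory <- trajectory[c(TRUE, diff(trajectory) < 0)]
  final <- solve_subset(st, active)
  new_pruned_network(model, active, st, final$objective_value, trajectory,
                     "min_flux", n_solves + 1L, restored = restored)
}

#' Prune a network by smallest biomass-flux impact
#'
#' Alternative pruning rule: at each step, remove the internal reaction whose
#' single deletion leaves the highest residual biomass flux (i.e. the
#' smallest impact), and stop when every possible single deletion drives the
#' biomass flux to zero. Deleting a reaction with zero flux at the current
#' optimum leaves the optimum exactly unchanged and is therefore always a
#' smallest-impact choice; when such reactions exist the earliest one is
#' removed without re-solving, otherwise the impact of every remaining
#' reaction is computed by re-solving and the earliest reaction attaining the
#' maximum residual flux (within `1e-6` relative tolerance) is removed.
#'
#' @inheritParams prune_min_flux
#' @return A `pruned_network`; see [prune_min_flux()].
#' @export
prune_biomass_impact <- function(model) {
  stopifnot(inherits(model, "network_model"))
  st <- prune_state(model)
  active <- st$internal
  sol <- solve_subset(st, active)
  n_solves <- 1L
  Z <- sol$objective_value
  if (Z < .ZERO_FLUX_TOL) {
    stop("full model has zero biomass flux; nothing to prune", call. = FALSE)
  }
  trajectory <- length(active)
  repeat {
    if (length(active) == 0L) break
    v <- sol$fluxes[seq_along(active)]
    zero <- which(abs(v) < .ZERO_FLUX_TOL)
    if (length(zero)) {
      drop <- zero[1L]                     # zero impact, earliest in order
      active <- active[-drop]
      sol$fluxes <- sol$fluxes[-drop]      # previous optimum stays optimal
    } else {
      impacts <- numeric(length(active))
      sols <- vector("list", length(active))
      for (k in seq_along(active)) {
        trial <- solve_subset(st, active[-k])
        n_solves <- n_solves + 1L
        impacts[k] <- trial$objective_value
        sols[[k]] <- trial
      }
      best <- max(impacts)
      if (best < .ZERO_FLUX_TOL) break     # every deletion kills biomass
      drop <- which(impacts >= best - 1e-6 * max(1, best))[1L]
      sol <- sols[[drop]]
      Z <- sol$objective_value
      active <- active[-drop]
    }
    trajectory <- c(trajectory, length(active))
  }
  final <- solve_subset(st, active)
  new_pruned_network(model, active, st, final$objective_value, trajectory,
                     "biomass_impact", n_solves + 1L)
}

#' @export
#' @method print pruned_network
print.pruned_network <- function(x, ...) {
  sz <- network_size(x)
  cat(sprintf(
    "<pruned_network> %s | %d reactions, %d metabolites | biomass flux %.4g\n",
    x$algorithm, sz[["reactions"]], sz[["metabolites"]], x$biomass_flux))
  cat(sprintf("  pruned from %d universe reactions in %d iterations\n",
              length(x$inclusion), length(x$trajectory) - 1L))
  invisible(x)
}

#' Size of a pruned network
#'
#' Reaction count is the number of retained internal reactions; metabolite
#' count is the number of metabolites participating in at least one retained
#' reaction.
#'
#' @param pruned A `pruned_network`.
#' @return Named numeric vector `c(metabolites = , reactions = )`.
#' @export
network_size <- function(pruned) {
  stopifnot(inherits(pruned, "pruned_network"))
  rxn <- enumerate_reactions(pruned$universe)
  rxn <- rxn[rxn$id %in% pruned$retained, ]
  mets <- unique(c(rxn$left, rxn$right, rxn$product))
  c(metabolites = length(mets), reactions = length(pruned$retained))
}

#' Rebuild the constraint-based model of a pruned network
#'
#' Reassembles a [build_model()] object containing only the retained internal
#' reactions, with the same nutrients, biomass and export setting used for
#' pruning. Useful for re-solving, exporting to SBML, or verifying that the
#' pruned network still supports biomass production.
#'
#' @param pruned A `pruned_network`.
#' @return A `network_model`.
#' @export
rebuild_model <- function(pruned) {
  stopifnot(inherits(pruned, "pruned_network"))
  build_model(pruned$universe, nutrients = pruned$nutrients,
              biomass = pruned$biomass, allow_export = pruned$allow_export,
              reactions = pruned$retained, bounds = pruned$bounds)
}

#' @describeIn prune_min_flux One row per universe reaction with a logical
#'   `retained` column.
#' @param x A `pruned_network`.
#' @param ... Unused.
#' @export
tidy.pruned_network <- function(x, ...) {
  tibble(reaction = enumerate_reactions(x$universe)$id,
         retained = as.logical(x$inclusion))
}

#' @describeIn prune_min_flux One-row summary (sizes, biomass flux,
#'   algorithm, iteration count).
#' @export
glance.pruned_network <- function(x, ...) {
  sz <- network_size(x)
  tibble(n_reactions = unname(sz[["reactions"]]),
         n_metabolites = unname(sz[["metabolites"]]),
         biomass_flux = x$biomass_flux,
         algorithm = x$algorithm,
         n_iterations = length(x$trajectory) - 1L,
         allow_export = x$allow_export)
}
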