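# metabolite-reaction participation edges (one edge per distinct pair)
participation_edges <- function(x, include_exchanges = FALSE) {
  if (inherits(x, "chem_universe")) {
    rxn <- enumerate_reactions(x)
  } else if (inherits(x, "pruned_network")) {
    rxn <- enumerate_reactions(x$universe)
    rxn <- rxn[rxn$id %in% x$retained, ]
  } else if (inherits(x, "network_model")) {
    rxn <- enumerate_reactions(x$universe)
    rxn <- rxn[rxn$id %in% x$reactions$id[x$reactions$type == "internal"], ]
  } else {
    stop("expected a chem_universe, network_model or pruned_network",
         call. = FALSE)
  }
  edges <- tibble(
    metabolite = c(rxn$left, rxn$right, rxn$product),
    reaction = rep(rxn$id, 3L))
  edges <- dplyr::distinct(edges)
  if (include_exchanges && inherits(x, "network_model")) {
    exch <- x$reactions[x$reactions$type != "internal", ]
    tr <- Matrix::summary(methods::as(x$S[, exch$id, drop = FALSE],
                                      "TsparseMatrix"))
    edges <- dplyr::bind_rows(edges, tibble(
      metabolite = rownames(x$S)[tr$i], reaction = exch$id[tr$j]))
  }
  edges
}

#' Bipartite metabolite-degree distribution
#'
#' Represents the network as an undirected bipartite graph with one node per
#' metabolite and per reaction and one edge per (metabolite, reaction)
#' participation, regardless of coefficient magnitude or role; only the
#' degrees of metabolite nodes enter the histogram. Metabolites touching no
#' reaction are excluded (a participation graph has no isolated nodes).
#' Exchange and biomass pseudo-reactions are excluded by default — they are
#' modeling artifacts, not chemistry.
#'
#' @param x A [chem_universe()], [build_model()] model or `pruned_network`.
#' @param include_exchanges Count exchange/biomass columns of a model as
#'   reaction nodes too (default `FALSE`).
#' @return A tibble of class `degree_histogram` with columns `degree` and
#'   `frequency` (fractions of metabolite nodes, summing to 1) and attribute
#'   `n_metabolites`.
#' @export
degree_distribution <- function(x, include_exchanges = FALSE) {
  edges <- participation_edges(x, include_exchanges)
  if (nrow(edges) == 0L) stop("network has no reactions", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(unique(edges$metabolite),
                                   unique(edges$reaction)),
                          type = rep(c(FALSE, TRUE),
                                     c(length(unique(edges$metabolite)),
                                       length(unique(edges$reaction))))))
  deg <- igraph::degree(g, v = igraph::V(g)[!igraph::V(g)$type])
  tab <- table(deg)
  out <- tibble(degree = as.integer(names(tab)),
                frequency = as.numeric(tab) / length(deg))
  attr(out, "n_metabolites") <- length(deg)
  class(out) <- c("degree_histogram", class(out))
  out
}

#' Normalized flux histogram
#'
#' Absolute fluxes are normalized to the largest absolute flux in the
#' solution and binned into 10 equal-width bins on `[0, 1]`; the final bin is
#' closed on the right so a normalized flux of exactly 1 lands in it.
#'
#' @param solution A [solve_fba()] result (or a bare numeric flux vector).
#' @return A tibble of class `flux_histogram` with columns `bin`, `lower`,
#'   `upper`, `frequency` (summing to 1).
#' @export
flux_distribution <- function(solution) {
  v <- if (inherits(solution, "flux_solution")) solution$fluxes else solution
  v <- abs(as.numeric(v))
  if (!length(v) || max(v) < .ZERO_FLUX_TOL) {
    stop("all fluxes are zero; normalization undefined", call. = FALSE)
  }
  vn <- v / max(v)
  bin <- pmin(floor(vn * 10) + 1L, 10L)
  counts <- tabulate(bin, nbins = 10L)
  tibble(bin = 1:10, lower = (0:9) / 10, upper = (1:10) / 10,
         frequency = counts / length(vn)) |>
    structure(class = c("flux_histogram", class(tibble())))
}

#' Reaction-to-metabolite connectivity ratio
#'
#' Number of (internal) reactions divided by number of metabolites; for
#' pruned networks only participating metabolites are counted.
#'
#' @param x A [chem_universe()], `network_model` or `pruned_network`.
#' @return A single numeric ratio.
#' @export
connectivity_ratio <- function(x) {
  if (inherits(x, "chem_universe")) {
    return(count_reactions(x$n_monomers, x$max_len) /
             count_metabolites(x$n_monomers, x$max_len))
  }
  if (inherits(x, "pruned_network")) {
    sz <- network_size(x)
    return(unname(sz[["reactions"]] / sz[["metabolites"]]))
  }
  if (inherits(x, "network_model")) {
    return(sum(x$reactions$type == "internal") / length(x$metabolites))
  }
  stop("expected a chem_universe, network_model or pruned_network",
       call. = FALSE)
}

#' Aggregate histograms into per-bin mean and standard deviation
#'
#' Aligns a list of degree or flux histograms on the union of their observed
#' degrees/bins (absent entries count as frequency 0) and returns the
#' per-entry mean and standard deviation across histograms.
#'
#' @param histograms A list of tibbles as returned by
#'   [degree_distribution()] or [flux_distribution()].
#' @return A tibble with the key column (`degree` or `bin`), `mean` and `sd`.
#' @export
aggregate_distributions <- function(histograms) {
  stopifnot(is.list(histograms), length(histograms) >= 2L)
  key <- if ("degree" %in% names(histograms[[1]])) "degree" else "bin"
  keys <- sort(unique(unlist(lapply(histograms, `[[`, key))))
  freq <- vapply(histograms, function(h) {
    f <- setNames(rep(0, length(keys)), keys)
    f[as.character(h[[key]])] <- h$frequency
    f
  }, numeric(length(keys)))
  freq <- matrix(freq, nrow = length(keys))
  out <- tibble(key = keys,
                mean = apply(freq, 1, mean),
                sd = apply(freq, 1, sd))
  names(out)[1] <- key
  out
}

#' Export the bipartite participation graph as an edge list
#'
#' Tab-separated `metabolite`, `reaction` columns, one row per edge, for
#' consumption by external graph tools.
#'
#' @inheritParams degree_distribution
#' @param path Output file path.
#' @export
write_edge_list <- function(x, path, include_exchanges = FALSE) {
  edges <- participation_edges(x, include_exchanges)
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
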