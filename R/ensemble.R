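#' Sample a crossed nutrient x biomass experimental design
#'
#' Draws `n_biomass_sets` sets of `biomass_size` precursor metabolites and
#' `n_nutrient_sets` sets of `nutrient_size` nutrient metabolites, each
#' uniformly without replacement from the universe's metabolites. The default
#' reproduction of the headline experiment uses 100 sets of 5 precursors and
#' 100 pairs of nutrients on the `A = 2, L = 5` universe.
#'
#' @param universe A [chem_universe()].
#' @param n_biomass_sets,biomass_size Number and size of precursor sets.
#' @param n_nutrient_sets,nutrient_size Number and size of nutrient sets.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param allow_overlap May a metabolite appear both as nutrient and
#'   precursor in a combination? Sampling is independent by default; set
#'   `FALSE` to reject nutrient sets overlapping any precursor set.
#' @return An `ensemble_design`: list of two tibbles, `biomass_sets`
#'   (`set_id`, `metabolite`) and `nutrient_sets` (`set_id`, `metabolite`).
#' @export
sample_design <- function(universe, n_biomass_sets = 100, biomass_size = 5,
                          n_nutrient_sets = 100, nutrient_size = 2,
                          seed = 1L, allow_overlap = TRUE) {
  stopifnot(inherits(universe, "chem_universe"))
  mets <- enumerate_metabolites(universe)$id
  if (biomass_size > length(mets) || nutrient_size > length(mets)) {
    stop("set size exceeds the universe's metabolite count", call. = FALSE)
  }
  check_count(n_biomass_sets, "n_biomass_sets")
  check_count(n_nutrient_sets, "n_nutrient_sets")
  withr::with_seed(seed, {
    bm <- lapply(seq_len(n_biomass_sets), function(i) sample(mets, biomass_size))
    forbidden <- unique(unlist(bm))
    pool <- if (allow_overlap) mets else setdiff(mets, forbidden)
    if (length(pool) < nutrient_size) {
      stop("not enough metabolites for non-overlapping nutrient sets",
           call. = FALSE)
    }
    nt <- lapply(seq_len(n_nutrient_sets), function(i) sample(pool, nutrient_size))
  })
  structure(
    list(
      biomass_sets = tibble(
        set_id = rep(seq_len(n_biomass_sets), each = biomass_size),
        metabolite = unlist(bm)),
      nutrient_sets = tibble(
        set_id = rep(seq_len(n_nutrient_sets), each = nutrient_size),
        metabolite = unlist(nt)),
      seed = as.integer(seed)),
    class = "ensemble_design")
}

design_sets <- function(design_tbl) {
  split(design_tbl$metabolite, design_tbl$set_id)
}

#' Prune every nutrient x biomass combination of a design
#'
#' Runs the chosen pruning algorithm on the full universe model for every
#' combination of the design's nutrient and precursor sets, producing one
#' record per combination. Under `coefficients = "random_1_to_10"` each
#' biomass coefficient is an independent uniform integer in 1..10 drawn from
#' the record's own child seed; under `"unit"` all coefficients are 1.
#' Combinations whose full model cannot produce biomass are flagged
#' (`feasible = FALSE`) rather than dropped.
#'
#' @param universe A [chem_universe()].
#' @param design An [sample_design()] object.
#' @param allow_export Build models with export exchanges for every
#'   metabolite (`TRUE`) or none (`FALSE`).
#' @param algorithm `"min_flux"` or `"biomass_impact"`.
#' @param coefficients `"unit"` or `"random_1_to_10"`.
#' @param seed Master seed; per-record child seeds are derived from it, so
#'   identical inputs reproduce identical records.
#' @return A tibble with one row per combination: `biomass_set_id`,
#'   `nutrient_set_id`, `algorithm`, `coefficients`, `allow_export`, `seed`,
#'   `feasible`, `biomass_flux`, `n_retained`, and list-columns `inclusion`
#'   (0/1 integer vector over the universe reaction enumeration) and
#'   `trajectory`.
#' @export
run_ensemble <- function(universe, design, allow_export = TRUE,
                         algorithm = c("min_flux", "biomass_impact"),
                         coefficients = c("unit", "random_1_to_10"),
                         seed = 1L) {
  stopifnot(inherits(universe, "chem_universe"),
            inherits(design, "ensemble_design"))
  algorithm <- match.arg(algorithm)
  coefficients <- match.arg(coefficients)
  prune_fun <- switch(algorithm, min_flux = prune_min_flux,
                      biomass_impact = prune_biomass_impact)
  bm_sets <- design_sets(design$biomass_sets)
  nt_sets <- design_sets(design$nutrient_sets)
  grid <- tidyr::expand_grid(biomass_set_id = as.integer(names(bm_sets)),
                             nutrient_set_id = as.integer(names(nt_sets)))
  child_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max, nrow(grid)))
  n_univ_rxn <- count_reactions(universe$n_monomers, universe$max_len)

  rows <- purrr::pmap(
    list(grid$biomass_set_id, grid$nutrient_set_id, child_seeds),
    function(b, n, child) {
      precursors <- bm_sets[[as.character(b)]]
      coefs <- if (coefficients == "unit") {
        setNames(rep(1, length(precursors)), precursors)
      } else {
        setNames(withr::with_seed(child,
                                  sample.int(10L, length(precursors),
                                             replace = TRUE)),
                 precursors)
      }
      model <- build_model(universe, nutrients = nt_sets[[as.character(n)]],
                           biomass = coefs, allow_export = allow_export)
      full <- solve_fba(model)
      if (full$objective_value < .ZERO_FLUX_TOL) {
        return(tibble(biomass_set_id = b, nutrient_set_id = n,
                      seed = child, feasible = FALSE,
                      biomass_flux = 0, n_retained = NA_integer_,
                      inclusion = list(rep(0L, n_univ_rxn)),
                      trajectory = list(integer())))
      }
      p <- prune_fun(model)
      tibble(biomass_set_id = b, nutrient_set_id = n, seed = child,
             feasible = TRUE, biomass_flux = p$biomass_flux,
             n_retained = length(p$retained),
             inclusion = list(p$inclusion), trajectory = list(p$trajectory))
    })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(algorithm = algorithm, coefficients = coefficients,
                  allow_export = allow_export, .after = "nutrient_set_id")
}

#' Jaccard similarity of two binary inclusion vectors
#'
#' Intersection over union of the 1-positions. Two all-zero vectors are
#' defined to have similarity 1.
#'
#' @param a,b Equal-length binary (0/1 or logical) vectors.
#' @return A value in `[0, 1]`.
#' @examples
#' jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("inclusion vectors must have equal length", call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

pairwise_jaccard_mean <- function(vectors) {
  n <- length(vectors)
  if (n < 2L) return(c(mean = NA_real_, n_pairs = 0))
  pairs <- combn(n, 2)
  sims <- apply(pairs, 2, function(p) {
    jaccard_similarity(vectors[[p[1]]], vectors[[p[2]]])
  })
  c(mean = mean(sims), n_pairs = ncol(pairs))
}

#' Within-group composition similarity contrast
#'
#' For records from a crossed design, computes the mean pairwise Jaccard
#' similarity of inclusion vectors among records sharing a biomass set, and
#' among records sharing a nutrient set. When biomass composition shapes
#' network composition more than nutrient choice does, the within-biomass
#' mean exceeds the within-nutrient mean. Infeasible records are excluded;
#' groups with fewer than two records are skipped with a warning.
#'
#' @param records A [run_ensemble()] tibble.
#' @return A one-row tibble: `within_biomass`, `within_nutrient`,
#'   `n_pairs_biomass`, `n_pairs_nutrient`.
#' @export
grouping_contrast <- function(records) {
  records <- dplyr::filter(records, .data$feasible)
  if (nrow(records) < 2L) stop("need at least two feasible records", call. = FALSE)
  group_mean <- function(key) {
    groups <- split(records$inclusion, records[[key]])
    stats <- lapply(groups, pairwise_jaccard_mean)
    skipped <- sum(vapply(stats, function(s) s[["n_pairs"]] == 0, logical(1)))
    if (skipped > 0) {
      warning(sprintf("%d %s group(s) with < 2 records skipped", skipped, key),
              call. = FALSE)
    }
    means <- vapply(stats, function(s) s[["mean"]], numeric(1))
    npairs <- vapply(stats, function(s) s[["n_pairs"]], numeric(1))
    c(mean = sum(means * npairs, na.rm = TRUE) / sum(npairs),
      n_pairs = sum(npairs))
  }
  bm <- group_mean("biomass_set_id")
  nt <- group_mean("nutrient_set_id")
  tibble(within_biomass = bm[["mean"]], within_nutrient = nt[["mean"]],
         n_pairs_biomass = bm[["n_pairs"]], n_pairs_nutrient = nt[["n_pairs"]])
}

#' Scan pruned-network size statistics across set sizes
#'
#' For each combination of nutrient-set size and precursor-set size, prunes
#' `reps` independently sampled random combinations (minimum-flux rule) and
#' records the fraction of universe reactions pruned away,
#' `1 - retained / count_reactions(A, L)`, and the reaction-to-metabolite
#' ratio of the pruned network.
#'
#' @param universe A [chem_universe()].
#' @param nutrient_sizes,biomass_sizes Integer vectors of set sizes to cross.
#' @param reps Replicates per grid cell (>= 2).
#' @param seed Master seed.
#' @param allow_export Passed to [build_model()].
#' @return A tibble with one row per grid cell: `n_nutrients`,
#'   `n_precursors`, `n_success`, `mean_pruned_fraction`,
#'   `sd_pruned_fraction`, `mean_ratio`, `sd_ratio`.
#' @export
scan_set_sizes <- function(universe, nutrient_sizes, biomass_sizes, reps = 10,
                           seed = 1L, allow_export = TRUE) {
  stopifnot(inherits(universe, "chem_universe"), reps >= 2)
  mets <- enumerate_metabolites(universe)$id
  n_rxn <- count_reactions(universe$n_monomers, universe$max_len)
  grid <- tidyr::expand_grid(n_nutrients = as.integer(nutrient_sizes),
                             n_precursors = as.integer(biomass_sizes))
  cell_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max, nrow(grid)))
  rows <- purrr::pmap(list(grid$n_nutrients, grid$n_precursors, cell_seeds),
    function(ns, bs, cseed) {
      fracs <- ratios <- numeric(0)
      rep_seeds <- withr::with_seed(cseed, sample.int(.Machine$integer.max, reps))
      for (r in seq_len(reps)) {
        draw <- withr::with_seed(rep_seeds[r], list(
          nutrients = sample(mets, ns), precursors = sample(mets, bs)))
        model <- build_model(universe, nutrients = draw$nutrients,
                             biomass = draw$precursors,
                             allow_export = allow_export)
        if (solve_fba(model)$objective_value < .ZERO_FLUX_TOL) next
        p <- prune_min_flux(model)
        sz <- network_size(p)
        fracs <- c(fracs, 1 - length(p$retained) / n_rxn)
        ratios <- c(ratios, sz[["reactions"]] / sz[["metabolites"]])
      }
      tibble(n_nutrients = ns, n_precursors = bs, n_success = length(fracs),
             mean_pruned_fraction = mean(fracs), sd_pruned_fraction = sd(fracs),
             mean_ratio = mean(ratios), sd_ratio = sd(ratios))
    })
  dplyr::bind_rows(rows)
}
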