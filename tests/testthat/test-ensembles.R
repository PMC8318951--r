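test_that("design sampling is seeded, sized, and rejects impossible sizes", {
  u <- chem_universe(2, 5)
  d <- sample_design(u, 100, 5, 100, 2, seed = 1)
  expect_equal(dplyr::n_distinct(d$biomass_sets$set_id), 100)
  expect_equal(dplyr::n_distinct(d$nutrient_sets$set_id), 100)
  expect_true(all(table(d$biomass_sets$set_id) == 5))
  expect_true(all(table(d$nutrient_sets$set_id) == 2))
  # without replacement within a set
  per_set <- split(d$biomass_sets$metabolite, d$biomass_sets$set_id)
  expect_true(all(vapply(per_set, anyDuplicated, integer(1)) == 0))
  expect_identical(d, sample_design(u, 100, 5, 100, 2, seed = 1))
  expect_false(identical(d, sample_design(u, 100, 5, 100, 2, seed = 2)))
  expect_error(sample_design(u, 10, 63, 10, 2), "exceeds")
  # full-universe set is the single possible set
  d_full <- sample_design(u, 1, 62, 1, 2, seed = 9)
  expect_setequal(d_full$biomass_sets$metabolite, enumerate_metabolites(u)$id)
})

test_that("ensembles produce one reproducible record per combination", {
  u <- chem_universe(2, 4)
  d <- sample_design(u, 3, 3, 3, 2, seed = 2)
  r <- run_ensemble(u, d, seed = 2)
  expect_equal(nrow(r), 9)
  expect_true(all(lengths(r$inclusion) ==
                    count_reactions(u$n_monomers, u$max_len)))
  expect_true(all(r$biomass_flux[r$feasible] > 0))
  expect_true(all(vapply(r$inclusion[r$feasible], sum, numeric(1)) ==
                    r$n_retained[r$feasible]))
  expect_identical(r, run_ensemble(u, d, seed = 2))
})

test_that("random biomass coefficients are integers in 1..10 per record", {
  u <- chem_universe(2, 4)
  d <- sample_design(u, 3, 3, 2, 2, seed = 4)
  r_unit <- run_ensemble(u, d, coefficients = "unit", seed = 4)
  r_rand <- run_ensemble(u, d, coefficients = "random_1_to_10", seed = 4)
  expect_equal(nrow(r_rand), 6)
  # same combinations, potentially different pruned nets
  expect_identical(r_unit[c("biomass_set_id", "nutrient_set_id")],
                   r_rand[c("biomass_set_id", "nutrient_set_id")])
  # coefficients affect the record seed-reproducibly
  expect_identical(r_rand, run_ensemble(u, d, coefficients = "random_1_to_10",
                                        seed = 4))
})

test_that("jaccard similarity follows its set definition", {
  expect_equal(jaccard_similarity(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 1)
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("grouping contrast is exact on constructed record sets", {
  base <- tibble::tibble(
    biomass_set_id = rep(1:2, each = 2),
    nutrient_set_id = rep(1:2, times = 2),
    feasible = TRUE)
  # inclusion depends only on the biomass set -> within-biomass mean is 1
  vecs <- list(c(1L,1L,0L), c(1L,1L,0L), c(0L,1L,1L), c(0L,1L,1L))
  r <- dplyr::mutate(base, inclusion = vecs)
  gc <- grouping_contrast(r)
  expect_equal(gc$within_biomass, 1)
  expect_equal(gc$within_nutrient, 1 / 3)  # J({1,2},{2,3}) in both groups
  # identical records -> both means 1
  r2 <- dplyr::mutate(base, inclusion = rep(list(c(1L,0L,1L)), 4))
  gc2 <- grouping_contrast(r2)
  expect_equal(gc2$within_biomass, 1)
  expect_equal(gc2$within_nutrient, 1)
})

test_that("set-size scans report pruned fractions and ratios in range", {
  u <- chem_universe(2, 4)
  sc <- scan_set_sizes(u, nutrient_sizes = 2, biomass_sizes = c(2, 4),
                       reps = 4, seed = 8)
  expect_equal(nrow(sc), 2)
  expect_true(all(sc$n_success >= 1))
  expect_true(all(sc$mean_pruned_fraction > 0 & sc$mean_pruned_fraction < 1))
  expect_true(all(sc$mean_ratio > 0))
})

test_that("ensemble records round-trip through the on-disk formats", {
  u <- chem_universe(2, 3)
  d <- sample_design(u, 2, 2, 2, 2, seed = 6)
  r <- run_ensemble(u, d, seed = 6)
  out <- tempfile()
  write_ensemble(r, u, out)
  expect_true(all(file.exists(file.path(
    out, c("records.csv", "records.jsonl", "inclusion.csv")))))
  inc <- read.csv(file.path(out, "inclusion.csv"), check.names = FALSE)
  feas <- r[r$feasible, ]
  expect_equal(nrow(inc), nrow(feas))
  expect_equal(ncol(inc), 2 + count_reactions(2, 3))
  expect_equal(unname(as.matrix(inc[, -(1:2)])[1, ]),
               as.numeric(feas$inclusion[[1]]))
  jl <- readLines(file.path(out, "records.jsonl"))
  expect_equal(length(jl), nrow(r))
  rec1 <- jsonlite::fromJSON(jl[1])
  expect_equal(rec1$inclusion, r$inclusion[[1]])
})
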