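test_that("model assembly has the expected exchange structure", {
  u <- chem_universe(2, 5)
  m <- build_model(u, nutrients = c("aa", "bb"),
                   biomass = c(ab = 1, ba = 1, aaa = 1, bbb = 1, abab = 1))
  counts <- table(m$reactions$type)
  expect_equal(as.integer(counts[c("internal", "import", "export", "biomass")]),
               c(196L, 2L, 62L, 1L))
  m2 <- build_model(u, nutrients = "aa", biomass = "ab", allow_export = FALSE)
  expect_false("export" %in% m2$reactions$type)
  expect_error(build_model(u, nutrients = "zz", biomass = "ab"), "zz")
  expect_error(build_model(u, nutrients = "aa", biomass = character()))
})

test_that("monomer balance fixes the toy optimum at half the import bound", {
  for (U in c(10, 100, 640)) {
    sol <- solve_fba(toy_model(import_ub = U))
    expect_equal(sol$objective_value, U / 2, tolerance = 1e-9)
    expect_lt(sol$residual, 1e-6)
    expect_equal(sol$status, "optimal")
  }
})

test_that("no imports means no biomass: mass cannot be created", {
  u <- chem_universe(2, 3)
  m <- build_model(u, nutrients = character(), biomass = "ab")
  expect_equal(solve_fba(m)$objective_value, 0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy steady state and bounds on random models", {
  u <- chem_universe(2, 4)
  mets <- enumerate_metabolites(u)$id
  for (seed in 1:5) {
    draw <- withr::with_seed(seed, list(n = sample(mets, 2), b = sample(mets, 3)))
    m <- build_model(u, nutrients = draw$n, biomass = draw$b,
                     allow_export = seed %% 2 == 0)
    sol <- solve_fba(m)
    expect_lt(sol$residual, 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lb - 1e-9))
    expect_true(all(sol$fluxes <= m$reactions$ub + 1e-9))
    expect_gte(sol$objective_value, -1e-12)
  }
})

test_that("LP kernel agrees with an external solver on random box LPs", {
  instances <- withr::with_seed(42, lapply(1:6, function(i) {
    m <- sample(3:6, 1); n <- sample(8:14, 1)
    list(c = round(runif(n, -1, 1), 3),
         A = matrix(round(rnorm(m * n), 3), m, n),
         lb = round(-runif(n, 0, 5), 3),
         ub = round(runif(n, 0, 5), 3))
  }))
  ours <- vapply(instances, function(ins) {
    stringchem:::lp_solve(ins$A, ins$lb, ins$ub, ins$c,
                          paste0("v", seq_along(ins$c)))$objective_value
  }, numeric(1))
  oracle <- run_python_oracle(c(
    "import json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "objs = []",
    "for ins in json.load(open(IN)):",
    "    c = np.array(ins['c']); A = np.array(ins['A'])",
    "    res = linprog(-c, A_eq=A, b_eq=np.zeros(A.shape[0]),",
    "                  bounds=list(zip(ins['lb'], ins['ub'])), method='highs')",
    "    objs.append(-res.fun)",
    "json.dump(objs, open(OUT, 'w'))"),
    lapply(instances, function(ins) {
      list(c = ins$c, A = apply(ins$A, 1, identity, simplify = FALSE),
           lb = ins$lb, ub = ins$ub)
    }))
  expect_false(is.null(oracle))
  expect_equal(ours, as.numeric(oracle), tolerance = 1e-7)
})

test_that("raising an import bound never decreases the optimum; scaling doubles it", {
  u <- chem_universe(2, 3)
  base <- model_bounds()
  obj_at <- function(ub) {
    b <- base; b$import[2] <- ub
    solve_fba(build_model(u, nutrients = c("ab", "ba"), biomass = "aab",
                          bounds = b))$objective_value
  }
  objs <- vapply(c(10, 20, 50, 100), obj_at, numeric(1))
  expect_true(all(diff(objs) >= -1e-9))
  expect_equal(obj_at(20), 2 * obj_at(10), tolerance = 1e-8)
})

test_that("single-deletion impacts equal brute-force re-solves", {
  u <- chem_universe(2, 3)
  m <- build_model(u, nutrients = "ab", biomass = c(aab = 1, ba = 1))
  sol <- solve_fba(m)
  fast <- single_deletion_impacts(m, sol)
  internal <- m$reactions$id[m$reactions$type == "internal"]
  brute <- vapply(internal, function(r) {
    j <- match(r, m$reactions$id)
    lb <- m$reactions$lb; ub <- m$reactions$ub
    lb[j] <- 0; ub[j] <- 0
    stringchem:::lp_solve(as.matrix(m$S), lb, ub, m$reactions$obj,
                          m$reactions$id)$objective_value
  }, numeric(1))
  expect_equal(fast$objective_value, unname(brute), tolerance = 1e-8)
  # deleting the only route to the sole precursor kills biomass
  toy <- toy_model()
  imp <- single_deletion_impacts(toy)
  expect_equal(imp$objective_value[imp$reaction == "a+a->aa"], 0,
               tolerance = 1e-9)
})

test_that("flux solutions tidy into per-reaction tibbles", {
  sol <- solve_fba(toy_model())
  td <- tidy(sol)
  expect_named(td, c("reaction", "type", "flux"))
  expect_equal(nrow(td), 5)  # 1 internal + 1 import + 2 exports + biomass
  g <- glance(sol)
  expect_equal(g$status, "optimal")
})
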