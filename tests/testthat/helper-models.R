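# Shared fixtures, all built in code.

# one-monomer toy: metabolites {a, aa}, single reaction a + a <-> aa
toy_model <- function(allow_export = TRUE, import_ub = 100) {
  b <- model_bounds()
  b$import[2] <- import_ub
  build_model(chem_universe(1, 2), nutrients = "a", biomass = "aa",
              allow_export = allow_export, bounds = b)
}

# deterministic sampler for (nutrients, precursors) combos on a universe;
# returns only combos whose full model supports biomass production
feasible_combos <- function(universe, n, nutrient_size = 2, biomass_size = 5,
                            allow_export = TRUE, seed = 1,
                            require_both_variants = FALSE, max_tries = 20 * n) {
  mets <- enumerate_metabolites(universe)$id
  draws <- withr::with_seed(seed, lapply(seq_len(max_tries), function(i) {
    list(nutrients = sample(mets, nutrient_size),
         precursors = sample(mets, biomass_size))
  }))
  out <- list()
  for (d in draws) {
    if (length(out) >= n) break
    m <- build_model(universe, d$nutrients, d$precursors,
                     allow_export = allow_export)
    if (solve_fba(m)$objective_value < 1e-9) next
    if (require_both_variants) {
      m2 <- build_model(universe, d$nutrients, d$precursors,
                        allow_export = !allow_export)
      if (solve_fba(m2)$objective_value < 1e-9) next
    }
    out[[length(out) + 1L]] <- d
  }
  out
}

# run an external python one-liner with input/output JSON files
run_python_oracle <- function(code, input) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(input, infile, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(sprintf("IN = %s", deparse(infile)),
               sprintf("OUT = %s", deparse(outfile)), code), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}
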