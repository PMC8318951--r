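test_that("universe export writes all artifacts and respects the size guard", {
  u <- chem_universe(3, 2)
  out <- tempfile()
  write_universe(u, out)
  files <- c("metabolites.tsv", "reactions.tsv", "stoich_matrix.csv",
             "stoich_triplets.tsv", "universe.sbml")
  expect_true(all(file.exists(file.path(out, files))))
  mets <- read.delim(file.path(out, "metabolites.tsv"))
  expect_equal(nrow(mets), 12)
  rxns <- read.delim(file.path(out, "reactions.tsv"))
  expect_equal(nrow(rxns), 9)
  # written matrix re-read equals the in-memory matrix
  S <- build_stoichiometric_matrix(u)
  expect_equal(as.matrix(read_stoich_csv(file.path(out, "stoich_matrix.csv"))),
               as.matrix(S))
  expect_error(write_universe(chem_universe(4, 10), tempfile()), "force")
})

test_that("SBML export carries species, reactions, bounds and objective", {
  u <- chem_universe(3, 2)
  path <- tempfile(fileext = ".sbml")
  write_sbml(u, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  expect_length(xml2::xml_find_all(doc, ".//sbml:species", ns), 12)
  expect_length(xml2::xml_find_all(doc, ".//sbml:reaction", ns), 9)

  m <- toy_model()
  path2 <- tempfile(fileext = ".sbml")
  write_sbml(m, path2)
  doc2 <- xml2::read_xml(path2)
  ns2 <- xml2::xml_ns_rename(xml2::xml_ns(doc2), d1 = "sbml")
  expect_length(xml2::xml_find_all(doc2, ".//sbml:species", ns2), 2)
  expect_length(xml2::xml_find_all(doc2, ".//sbml:reaction", ns2), 5)
  obj <- xml2::xml_find_all(doc2, ".//fbc:fluxObjective", ns2)
  expect_equal(xml2::xml_attr(obj, "reaction"), "R_BIOMASS")
  # every reaction references declared bound parameters
  pars <- xml2::xml_attr(xml2::xml_find_all(doc2, ".//sbml:parameter", ns2), "id")
  lbs <- xml2::xml_attr(xml2::xml_find_all(doc2, ".//sbml:reaction", ns2),
                        "lowerFluxBound")
  expect_true(all(lbs %in% pars))
})

test_that("an external constraint-based solver reproduces our optimum from SBML", {
  u <- chem_universe(2, 3)
  m <- build_model(u, nutrients = "ab", biomass = c(aab = 1, ba = 1))
  ours <- solve_fba(m)$objective_value
  path <- tempfile(fileext = ".sbml")
  write_sbml(m, path)
  oracle <- run_python_oracle(c(
    "import json, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    "path = json.load(open(IN))['path']",
    "model = cobra.io.read_sbml_model(path)",
    "json.dump({'objective': model.slim_optimize()}, open(OUT, 'w'))"),
    list(path = path))
  expect_false(is.null(oracle))
  expect_equal(ours, oracle$objective, tolerance = 1e-6)
})

test_that("the command-line interface runs end to end on a small universe", {
  cli <- system.file("cli", "stringchem.R", package = "stringchem")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")

  out1 <- tempfile()
  res1 <- system2(rscript, c(cli, "generate", "-A", "2", "-L", "2",
                             "--out", out1), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out1, "stoich_matrix.csv")))
  expect_true(file.exists(file.path(out1, "config.json")))

  out2 <- tempfile()
  res2 <- system2(rscript, c(cli, "prune", "-A", "1", "-L", "2",
                             "--nutrients", "a", "--precursors", "aa",
                             "--both", "--out", out2),
                  stdout = TRUE, stderr = TRUE)
  pj <- file.path(out2, "pruned_min_flux.json")
  expect_true(file.exists(pj))
  expect_identical(read_pruned_json(pj)$retained, "a+a->aa")
  expect_true(file.exists(file.path(out2, "pruned_biomass_impact.json")))
  expect_true(any(grepl("Jaccard", res2)))

  # determinism: the same config twice gives identical outputs
  out3 <- tempfile()
  system2(rscript, c(cli, "prune", "-A", "1", "-L", "2", "--nutrients", "a",
                     "--precursors", "aa", "--out", out3),
          stdout = TRUE, stderr = TRUE)
  expect_identical(readLines(file.path(out3, "pruned_min_flux.json")),
                   readLines(file.path(out2, "pruned_min_flux.json")))

  out4 <- tempfile()
  res4 <- system2(rscript, c(cli, "ensemble", "-A", "2", "-L", "3",
                             "--n-biomass", "2", "--biomass-size", "2",
                             "--n-nutrients", "2", "--nutrient-size", "2",
                             "--seed", "3", "--out", out4),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out4, "grouping_contrast.csv")))

  out5 <- tempfile()
  res5 <- system2(rscript, c(cli, "stats", "--pruned",
                             shQuote(file.path(out2, "pruned_*.json")),
                             "--out", out5), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out5, "degree_distribution.csv")))
  expect_true(file.exists(file.path(out5, "connectivity.csv")))
})
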