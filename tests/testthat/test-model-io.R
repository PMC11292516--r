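# SBML round-tripping, database loading and diet application.

test_that("SBML write/read roundtrip is lossless", {
  g <- make_toy_genus(n_species = 3, seed = 4)
  for (m in g$models[1:2]) {
    f <- tempfile(fileext = ".xml")
    write_model(m, f)
    m2 <- read_model(f)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$metabolites$id, m$metabolites$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_true(all(abs(m2$S - m$S) == 0))
    expect_identical(m2$objective, m$objective)
    expect_identical(m2$metabolites$formula, m$metabolites$formula)
    expect_identical(m2$metabolites$compartment, m$metabolites$compartment)
  }
})

test_that("a PGMM survives the SBML + sidecar roundtrip with its objective", {
  g <- make_toy_genus(n_species = 3, seed = 4)
  pg <- build_pgmm(g$models, g$databases$biomass)
  f <- tempfile(fileext = ".xml")
  write_pgmm(pg, f)
  pg2 <- read_pgmm(f)
  expect_identical(pg2$model$objective, "panBiomass")
  expect_identical(pg2$species_list, pg$species_list)
  expect_equal(pg2$presence_matrix, pg$presence_matrix)
  expect_equal(as.numeric(pg2$current_probabilities),
               as.numeric(pg$current_probabilities))
  expect_true(all(abs(pg2$model$S - pg$model$S) == 0))
})

test_that("malformed SBML is rejected with a diagnostic", {
  f <- tempfile(fileext = ".xml")
  writeLines("this is not xml <<", f)
  expect_error(read_model(f), "format error")

  # reaction referencing an undeclared species
  g <- make_toy_genus(n_species = 2, seed = 1)
  f2 <- tempfile(fileext = ".xml")
  write_model(g$models[[1]], f2)
  txt <- readLines(f2)
  txt <- sub('species="M_nut__91__c__93__"', 'species="M_ghost__91__c__93__"',
             txt)
  writeLines(txt, f2)
  expect_error(read_model(f2), "integrity error")

  expect_error(read_model(tempfile()), "not found")
})

test_that("duplicate reaction ids in SBML are an integrity error", {
  g <- make_toy_genus(n_species = 2, seed = 1)
  f <- tempfile(fileext = ".xml")
  write_model(g$models[[1]], f)
  doc <- readLines(f)
  rx <- grep('<reaction id="R_NUTt"', doc, value = TRUE)
  i <- grep('<reaction id="R_NUTCLV"', doc)
  doc[i] <- sub('id="R_NUTCLV"', 'id="R_NUTt"', doc[i])
  writeLines(doc, f)
  expect_error(read_model(f), "integrity error.*duplicate")
})

test_that("models cannot be built degenerate", {
  expect_error(
    metabolic_model("empty",
                    data.frame(id = "a[c]", compartment = "c"),
                    data.frame(id = character(0),
                               lower_bound = numeric(0),
                               upper_bound = numeric(0)),
                    matrix(0, 1, 0), "none"),
    "degenerate|objective")
  m <- chain_model()
  expect_error(set_bounds(m, "ghost", lower = 0), "unknown reaction")
  bad <- set_bounds(m, "AB", lower = 5, upper = -5)
  expect_error(validate_model(bad), "lower_bound > upper_bound")
})

test_that("COBRApy independently reads our SBML and agrees on the optimum", {
  g <- make_toy_genus(n_species = 3, seed = 9)
  m <- suppressWarnings(apply_diet(g$models[[2]], g$diet))
  f <- tempfile(fileext = ".xml")
  write_model(m, f)
  ours <- fba(m)$objective_value
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print(len(m.reactions), len(m.metabolites), m.slim_optimize())"), script)
  out <- suppressWarnings(
    system2("python", c(script, f), stdout = TRUE, stderr = FALSE))
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(vals[1]), nrow(m$reactions))
  expect_equal(as.integer(vals[2]), nrow(m$metabolites))
  expect_equal(as.numeric(vals[3]), ours, tolerance = 1e-6)
})

test_that("databases load from TSV and reject bad rows", {
  rt <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tstoichiometry\tlower_bound\tupper_bound\tsubsystem",
               "RA\tra\ta[c] -> b[c]\t0\t1000\tCore",
               "RB\trb\t2 b[c] <=> c[c]\t-1000\t1000\tCore"), rt)
  bt <- tempfile(fileext = ".tsv")
  writeLines(c(paste("species_id", "reaction_id", "stoichiometry",
                     "biomass_metabolite", "drain_id", sep = "\t"),
               "spA\tBIO_A\ta[c] -> bioA[c]\tbioA[c]\tDM_A",
               "spB\tBIO_B\t2 b[c] -> bioB[c]\tbioB[c]\tDM_B"), bt)
  dbs <- load_databases(rt, bt)
  expect_length(dbs$reactions, 2)
  expect_length(dbs$biomass, 2)
  expect_equal(db_lookup(dbs$reactions, "RB")$stoichiometry,
               c("b[c]" = -2, "c[c]" = 1), ignore_attr = TRUE)
  expect_equal(db_lookup(dbs$biomass, "spB")$biomass_metabolite, "bioB[c]")
  expect_error(db_lookup(dbs$reactions, "nope"), "lookup error")

  # unparseable stoichiometry names the row
  writeLines(c("id\tname\tstoichiometry\tlower_bound\tupper_bound\tsubsystem",
               "RX\trx\tgibberish without arrow\t0\t1\tCore"), rt)
  expect_error(load_databases(rt, bt), "row 1.*RX")

  # conflicting duplicate stoichiometry
  writeLines(c("id\tname\tstoichiometry\tlower_bound\tupper_bound\tsubsystem",
               "RA\tra\ta[c] -> b[c]\t0\t1000\tCore",
               "RA\tra\ta[c] -> 2 b[c]\t0\t1000\tCore"), rt)
  expect_error(load_databases(rt, bt), "conflict error")
})

test_that("diet application follows the VMH sign convention", {
  m <- chain_model()
  d <- diet_spec("d", data.frame(reaction_id = "EX_a(e)",
                                 lower_bound = -4, upper_bound = 1000))
  m2 <- apply_diet(m, d)
  j <- match("EX_a(e)", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[j], -4)
  # idempotence
  m3 <- apply_diet(m2, d)
  expect_equal(m3$reactions$lower_bound, m2$reactions$lower_bound)
  expect_equal(m3$reactions$upper_bound, m2$reactions$upper_bound)
  # unlisted exchanges are uptake-closed, secretion untouched
  g <- make_toy_genus(n_species = 2, seed = 2)
  sp <- g$models[[1]]
  d2 <- diet_spec("nut_only", data.frame(reaction_id = "EX_nut(e)",
                                         lower_bound = -10,
                                         upper_bound = 1000))
  sp2 <- apply_diet(sp, d2, close_unlisted = TRUE)
  others <- setdiff(exchange_reactions(sp2), "EX_nut(e)")
  jo <- match(others, sp2$reactions$id)
  expect_true(all(sp2$reactions$lower_bound[jo] == 0))
  expect_true(all(sp2$reactions$upper_bound[jo] > 0))
  # unknown diet entry warns but does not fail
  d3 <- diet_spec("ghost", data.frame(reaction_id = "EX_ghost(e)",
                                      lower_bound = -1, upper_bound = 1))
  expect_warning(apply_diet(sp, d3), "not in model")
})

test_that("an empty diet with closed unlisted uptakes starves the model", {
  m <- chain_model()
  empty <- diet_spec("empty", data.frame(reaction_id = character(0),
                                         lower_bound = numeric(0),
                                         upper_bound = numeric(0)))
  starved <- apply_diet(m, empty, close_unlisted = TRUE)
  expect_equal(fba(starved)$objective_value, 0, tolerance = 1e-9)
  # versus 10 with the carbon source open (uptake bound 10)
  expect_equal(fba(m)$objective_value, 10, tolerance = 1e-9)
})

test_that("diet tables read in both dialects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tuptake", "EX_a(e)\t7"), f)
  d <- read_diet(f, "two_col")
  expect_equal(d$bounds$lower_bound, -7)
  expect_equal(d$bounds$upper_bound, 1000)
  d0 <- diet_spec("rt", data.frame(reaction_id = c("EX_a(e)", "EX_b(e)"),
                                   lower_bound = c(-5, 0),
                                   upper_bound = c(100, 10)))
  f2 <- tempfile(fileext = ".tsv")
  write_diet(d0, f2)
  d2 <- read_diet(f2)
  expect_equal(d2$bounds, d0$bounds)
  expect_error(diet_spec("bad", data.frame(reaction_id = "x",
                                           lower_bound = 1,
                                           upper_bound = -1)),
               "lower_bound > upper_bound")
})
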