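# Community assembly: compartmentalization, lumped biomass, the four
# community types, personalization.

test_that("compartmentalization prefixes internals and shares the lumen", {
  up <- union_pair()
  cm <- compartmentalize_member(up$models$spA, "A")
  expect_true(all(grepl("^A_", cm$reactions$id)))
  expect_true("A_a[c]" %in% cm$metabolites$id)
  expect_true("a[u]" %in% cm$metabolites$id)   # lumen stays unprefixed
  expect_true("A_TR_a" %in% cm$reactions$id)   # exchange became transport
  expect_false("R1" %in% cm$reactions$id)
  expect_error(compartmentalize_member(cm, "A"), "tag collision")
})

test_that("members with a common exchange metabolite meet in one lumen species", {
  g <- make_toy_genus(n_species = 2, seed = 2)
  ab <- c(0.5, 0.5); names(ab) <- g$species
  comm <- suppressWarnings(
    build_community(ab, g$models, "gsmm", g$diet, g$databases$biomass))
  expect_equal(sum(comm$model$metabolites$id == "nut[u]"), 1L)
  # both members transport to it
  trs <- grep("_TR_nut$", comm$model$reactions$id, value = TRUE)
  expect_length(trs, 2L)
})

test_that("lumped biomass averages coefficients per convention", {
  up <- union_pair()
  db <- up$biomass_db
  # identical biomass reactions -> lumped equals either one
  db2 <- db
  db2$spB$stoichiometry <- db$spA$stoichiometry
  db2$spB$biomass_metabolite <- "bioA[c]"
  lump <- build_lumped_pan_biomass(up$models, db2)
  j <- match("lumpedBiomass", lump$reactions$id)
  expect_equal(lump$S["a[c]", j], -1)
  # coefficients 2 and 4 -> mean 3 (shared metabolite)
  db3 <- db
  db3$spA$stoichiometry <- parse_stoichiometry("2 a[c] -> bioA[c]")
  db3$spB$stoichiometry <- parse_stoichiometry("4 a[c] -> bioB[c]")
  lump3 <- build_lumped_pan_biomass(up$models, db3)
  j <- match("lumpedBiomass", lump3$reactions$id)
  expect_equal(lump3$S["a[c]", j], -3)
  # metabolite in 1 of 2 species: present-only mean 1, zero-filled 0.5
  db4 <- db
  db4$spA$stoichiometry <- parse_stoichiometry("a[c] + b[c] -> bioA[c]")
  db4$spB$stoichiometry <- parse_stoichiometry("a[c] -> bioB[c]")
  lp <- build_lumped_pan_biomass(up$models, db4, mode = "present_only")
  lz <- build_lumped_pan_biomass(up$models, db4, mode = "zero_filled")
  jp <- match("lumpedBiomass", lp$reactions$id)
  jz <- match("lumpedBiomass", lz$reactions$id)
  expect_equal(lp$S["b[c]", jp], -1)
  expect_equal(lz$S["b[c]", jz], -0.5)
})

test_that("a single-member community reproduces its member", {
  g <- make_toy_genus(n_species = 3, seed = 3)
  sp <- g$species[1]
  ab <- c(1); names(ab) <- sp
  comm <- suppressWarnings(
    build_community(ab, g$models[sp], "gsmm", g$diet, g$databases$biomass))
  member <- suppressWarnings(apply_diet(g$models[[sp]], g$diet))
  expect_equal(fba(comm)$objective_value, fba(member)$objective_value,
               tolerance = 1e-6)
  map <- lumen_ids_for(member)
  fm <- fva(member, names(map))
  fc <- fva(comm$model, unname(map))
  expect_equal(fc$max_flux, fm$max_flux, tolerance = 1e-6)
  expect_equal(fc$min_flux, fm$min_flux, tolerance = 1e-6)
})

test_that("two identical members at 0.5/0.5 match the single-member optimum", {
  g <- make_toy_genus(n_species = 3, seed = 3)
  sp <- g$species[1]
  ab <- c(0.5, 0.5); names(ab) <- c(sp, "twin")
  reg <- list(g$models[[sp]], g$models[[sp]]); names(reg) <- names(ab)
  db <- g$databases$biomass
  db$twin <- db[[sp]]
  comm <- suppressWarnings(
    build_community(ab, reg, "gsmm", g$diet, db))
  single <- suppressWarnings(
    build_community(stats::setNames(1, sp), g$models[sp], "gsmm",
                    g$diet, g$databases$biomass))
  expect_equal(fba(comm)$objective_value, fba(single)$objective_value,
               tolerance = 1e-6)
})

test_that("hybrid communities route species to GSMMs and genera to PGMMs", {
  g <- make_toy_genus(n_species = 3, seed = 3)
  pg <- build_pgmm(g$models, g$databases$biomass)
  ab <- c(0.5, 0.5); names(ab) <- c(g$species[1], "Genus1")
  reg <- list(g$models[[1]], pg); names(reg) <- names(ab)
  comm <- suppressWarnings(
    build_community(ab, reg, "hybrid", g$diet, g$databases$biomass))
  expect_setequal(comm$members$type, c("GSMM", "PGMM"))
  expect_true(any(grepl("panBiomass", comm$members$biomass_met)))
  expect_gt(fba(comm)$objective_value, 0)
  # PGMM members are refused in a gsmm-typed community
  expect_error(
    suppressWarnings(build_community(ab, reg, "gsmm", g$diet,
                                     g$databases$biomass)),
    "type is 'gsmm'")
  expect_error(
    suppressWarnings(build_community(
      stats::setNames(c(0.5, 0.5), c(g$species[1], "nope")),
      reg, "hybrid", g$diet, g$databases$biomass)),
    "unresolvable taxon")
})

test_that("personalization only moves biomass coefficients and silencing", {
  g <- make_toy_genus(n_species = 3, seed = 5)
  ab <- stats::setNames(c(0.5, 0.3, 0.2), g$species)
  comm <- suppressWarnings(
    build_community(ab, g$models, "gsmm", g$diet, g$databases$biomass))
  # fixed point
  same <- personalize_community(comm, ab)
  expect_equal(same$model$reactions$lower_bound,
               comm$model$reactions$lower_bound)
  expect_true(all(abs(same$model$S - comm$model$S) == 0))
  # renormalization
  two <- personalize_community(comm, stats::setNames(c(2, 2),
                                                     g$species[1:2]))
  expect_equal(sort(two$members$abundance), c(0, 0.5, 0.5))
  # zero-abundance member is silenced and matches the community without it
  drop3 <- personalize_community(comm, stats::setNames(c(0.5, 0.5, 0),
                                                       g$species))
  tag3 <- comm$members$member_id[comm$members$taxon == g$species[3]]
  j <- match(comm$member_reactions[[tag3]], drop3$model$reactions$id)
  expect_true(all(drop3$model$reactions$upper_bound[j] == 0))
  without <- suppressWarnings(
    build_community(stats::setNames(c(0.5, 0.5), g$species[1:2]),
                    g$models[1:2], "gsmm", g$diet, g$databases$biomass))
  expect_equal(fba(drop3)$objective_value, fba(without)$objective_value,
               tolerance = 1e-6)
  expect_error(personalize_community(comm, c(ghost = 1)),
               "absent from template")
})

test_that("member insertion order does not change community FVA", {
  g <- make_toy_genus(n_species = 3, seed = 7)
  ab <- stats::setNames(c(0.2, 0.3, 0.5), g$species)
  c1 <- suppressWarnings(
    build_community(ab, g$models, "gsmm", g$diet, g$databases$biomass))
  perm <- c(3, 1, 2)
  c2 <- suppressWarnings(
    build_community(ab[perm], g$models[perm], "gsmm", g$diet,
                    g$databases$biomass))
  ex <- sort(intersect(grep("^EX_", c1$model$reactions$id, value = TRUE),
                       grep("^EX_", c2$model$reactions$id, value = TRUE)))
  f1 <- fva(c1$model, ex)
  f2 <- fva(c2$model, ex)
  expect_equal(f1$max_flux, f2$max_flux, tolerance = 1e-6)
  expect_equal(f1$min_flux, f2$min_flux, tolerance = 1e-6)
})

test_that("community internals stay elementally balanced", {
  g <- make_toy_genus(n_species = 2, seed = 9)
  ab <- stats::setNames(c(0.6, 0.4), g$species)
  comm <- suppressWarnings(
    build_community(ab, g$models, "gsmm", g$diet, g$databases$biomass))
  skip_ids <- c(comm$community_biomass_id,
                grep("BIO_|biomass", comm$model$reactions$id, value = TRUE))
  bal <- check_mass_balance(comm$model, skip = skip_ids)
  expect_true(all(bal))
})
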