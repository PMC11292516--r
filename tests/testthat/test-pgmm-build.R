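# Merging species models into a PGMM: reaction union, presence matrix,
# panBiomass formulation, duplicate/futile pruning.

test_that("the union keeps each reaction once with the right presence rows", {
  up <- union_pair()
  un <- collect_unique_reactions(up$models, up$biomass_db)
  expect_setequal(un$draft$reactions$id, c("R1", "R2", "R3"))
  pm <- un$presence_matrix
  expect_equal(unname(pm["R1", ]), c(1L, 0L))
  expect_equal(unname(pm["R2", ]), c(1L, 1L))
  expect_equal(unname(pm["R3", ]), c(0L, 1L))
  # biomass machinery excluded from the union
  expect_false(any(c("BIO_A", "BIO_B", "DM_A", "DM_B") %in%
                     un$draft$reactions$id))
})

test_that("a single species maps onto itself with an all-ones column", {
  up <- union_pair()
  un <- collect_unique_reactions(up$models["spA"], up$biomass_db)
  expect_setequal(un$draft$reactions$id, c("R1", "R2"))
  expect_true(all(un$presence_matrix == 1L))
})

test_that("shared reactions merge to the widest bounds", {
  up <- union_pair()
  mods <- up$models
  # R2 carried with bounds (0, 10) in A and (-10, 5) in B
  mods$spA <- set_bounds(mods$spA, "R2", lower = 0, upper = 10)
  mods$spB <- set_bounds(mods$spB, "R2", lower = -10, upper = 5)
  un <- collect_unique_reactions(mods, up$biomass_db)
  j <- match("R2", un$draft$reactions$id)
  expect_equal(un$draft$reactions$lower_bound[j], -10)
  expect_equal(un$draft$reactions$upper_bound[j], 10)
})

test_that("conflicting stoichiometry or disjoint namespaces are refused", {
  up <- union_pair()
  mods <- up$models
  # same id, different stoichiometry
  j <- match("R2", mods$spB$reactions$id)
  mods$spB$S["a[c]", j] <- 2
  expect_error(collect_unique_reactions(mods, up$biomass_db),
               "conflict error.*R2")
  # disjoint reaction namespaces
  other <- build_model(
    "spC",
    list(list("z[e]", "C1"), list("z[c]", "C1"), list("bioC[c]", "C1")),
    list(list("Z1", "z[e] <=>", -10, 1000),
         list("Z2", "z[e] <=> z[c]", -1000, 1000),
         list("BIO_C", "z[c] -> bioC[c]", 0, 1000)),
    "BIO_C")
  db <- up$biomass_db
  db$spC <- list(species_id = "spC", reaction_id = "BIO_C",
                 stoichiometry = parse_stoichiometry("z[c] -> bioC[c]"),
                 biomass_metabolite = "bioC[c]", drain_id = NA_character_)
  expect_error(collect_unique_reactions(list(up$models$spA, other), db),
               "disjoint")
})

test_that("panBiomass enforces the species proportions s_i", {
  up <- union_pair()
  # n = 1: panBiomass optimum equals the species' own optimum
  pg1 <- build_pgmm(up$models["spA"], up$biomass_db, media = up$diet,
                    prune = FALSE)
  o_sp <- validate_growth(up$models$spA, up$diet)
  expect_equal(attr(pg1, "growth"), o_sp, tolerance = 1e-9)
  j <- match("panBiomass", pg1$model$reactions$id)
  expect_equal(pg1$model$S["bioA[c]", j], -1)

  # n = 2, s = (0.7, 0.3): species biomass fluxes split 0.7/0.3
  g <- make_toy_genus(n_species = 2, seed = 3)
  pg <- build_pgmm(g$models, g$databases$biomass, s = c(0.7, 0.3),
                   prune = FALSE)
  j <- match("panBiomass", pg$model$reactions$id)
  expect_equal(unname(pg$model$S[pg$species_biomass_mets, j]),
               c(-0.7, -0.3))
  md <- suppressWarnings(apply_diet(pg$model, g$diet))
  sol <- fba(md)
  v_pan <- sol$fluxes[["panBiomass"]]
  expect_gt(v_pan, 0)
  expect_equal(sol$fluxes[[pg$species_biomass_ids[1]]], 0.7 * v_pan,
               tolerance = 1e-6)
  expect_equal(sol$fluxes[[pg$species_biomass_ids[2]]], 0.3 * v_pan,
               tolerance = 1e-6)
})

test_that("exact duplicates collapse to one survivor with OR-merged presence", {
  up <- union_pair()
  mods <- up$models
  # spB carries R2 under a second name (sign-flipped, flipped bounds)
  m <- mods$spB
  S2 <- cbind(as.matrix(m$S),
              "R2_alias" = -as.matrix(m$S)[, match("R2", m$reactions$id)])
  rx2 <- rbind(m$reactions,
               data.frame(id = "R2_alias", name = "R2 alias",
                          lower_bound = -1000, upper_bound = 1000,
                          gene_rule = "", subsystem = "",
                          stringsAsFactors = FALSE))
  mods$spB <- metabolic_model(m$id, m$metabolites, rx2, S2, m$objective)
  pg <- build_pgmm(mods, up$biomass_db, media = up$diet, prune = TRUE)
  expect_false("R2_alias" %in% pg$model$reactions$id)
  expect_equal(unname(pg$presence_matrix["R2", ]), c(1L, 1L))
  expect_true("R2_alias" %in% attr(pg, "removed"))
})

test_that("a futile loop is pruned without hurting growth", {
  up <- union_pair()
  mods <- up$models
  m <- mods$spA
  # irreversible three-reaction cycle disconnected from biomass:
  # a[c] -> w[c] -> x[c] -> a[c] can carry unbounded flux on any medium
  mets <- rbind(m$metabolites,
                data.frame(id = c("w[c]", "x[c]"), name = c("w", "x"),
                           compartment = "c", formula = "C1", charge = 0L,
                           stringsAsFactors = FALSE))
  S2 <- rbind(as.matrix(m$S), "w[c]" = 0, "x[c]" = 0)
  is_a <- mets$id == "a[c]"; is_w <- mets$id == "w[c]"
  is_x <- mets$id == "x[c]"
  S2 <- cbind(S2,
              "LOOP1" = -1 * is_a + 1 * is_w,
              "LOOP2" = -1 * is_w + 1 * is_x,
              "LOOP3" = -1 * is_x + 1 * is_a)
  rx2 <- rbind(m$reactions,
               data.frame(id = c("LOOP1", "LOOP2", "LOOP3"),
                          name = c("l1", "l2", "l3"),
                          lower_bound = 0, upper_bound = 1000,
                          gene_rule = "", subsystem = "",
                          stringsAsFactors = FALSE))
  mods$spA <- metabolic_model(m$id, mets, rx2, S2, m$objective)
  o_before <- validate_growth(mods$spA, up$diet)
  pg <- build_pgmm(mods, up$biomass_db, media = up$diet, prune = TRUE)
  expect_true(all(c("LOOP1", "LOOP2", "LOOP3") %in% attr(pg, "removed")))
  expect_equal(attr(pg, "growth"), o_before, tolerance = 1e-6)
})

test_that("pruning is a fixed point on a clean genus", {
  up <- union_pair()
  pg0 <- build_pgmm(up$models, up$biomass_db, media = up$diet,
                    prune = FALSE)
  pg1 <- prune_duplicates_and_futile(pg0, up$diet)
  expect_identical(pg1$model$reactions$id, pg0$model$reactions$id)
  expect_equal(attr(pg1, "removed"), character(0))
  expect_equal(pg1$presence_matrix, pg0$presence_matrix)
})

test_that("union and presence invariants hold across random genera", {
  for (seed in c(11, 12, 13)) {
    g <- make_toy_genus(n_species = 4, seed = seed)
    un <- collect_unique_reactions(g$models, g$databases$biomass)
    # brute-force union oracle
    machinery <- c(g$biomass_table$reaction_id, g$biomass_table$drain_id)
    expected <- sort(unique(unlist(lapply(g$models, function(m)
      setdiff(m$reactions$id, machinery)))))
    expect_setequal(un$draft$reactions$id, expected)
    expect_true(all(rowSums(un$presence_matrix) >= 1))
    # column i restricted to its ones reproduces species i's reaction set
    for (i in seq_along(g$models)) {
      got <- rownames(un$presence_matrix)[un$presence_matrix[, i] == 1]
      expect_setequal(got, setdiff(g$models[[i]]$reactions$id, machinery))
    }
  }
})

test_that("growth validation reports the optimum and catches infeasibility", {
  up <- union_pair()
  expect_gt(validate_growth(up$models$spA, up$diet), 0)
  starved <- apply_diet(up$models$spA,
                        diet_spec("none", data.frame(
                          reaction_id = character(0),
                          lower_bound = numeric(0),
                          upper_bound = numeric(0))))
  expect_equal(validate_growth(starved), 0, tolerance = 1e-9)
})
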