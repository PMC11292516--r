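# Shared fixtures built in code: a hand-computable linear chain model, a
# pair of micro-models for union tests, and a two-species genus whose
# biomass byproducts give a known composition-dependent bandwidth.

# assemble a metabolic_model from equation strings
build_model <- function(id, mets, rxns, objective) {
  met_df <- do.call(rbind, lapply(mets, function(m)
    data.frame(id = m[[1]], name = m[[1]],
               compartment = sub("^.*\\[(.*)\\]$", "\\1", m[[1]]),
               formula = m[[2]], charge = 0L, stringsAsFactors = FALSE)))
  S <- matrix(0, nrow(met_df), length(rxns),
              dimnames = list(met_df$id, vapply(rxns, `[[`, character(1), 1)))
  rxn_df <- data.frame(
    id = colnames(S),
    name = colnames(S),
    lower_bound = vapply(rxns, function(r) r[[3]], numeric(1)),
    upper_bound = vapply(rxns, function(r) r[[4]], numeric(1)),
    gene_rule = "", subsystem = "", stringsAsFactors = FALSE)
  for (j in seq_along(rxns)) {
    st <- parse_stoichiometry(rxns[[j]][[2]])
    S[names(st), j] <- st
  }
  metabolic_model(id, met_df, rxn_df, S, objective)
}

# linear pathway with a unique optimal flux distribution:
# uptake a (max 10) -> convert -> biomass; optimum = 10
chain_model <- function() {
  build_model(
    "chain",
    list(list("a[e]", "C1"), list("a[c]", "C1"), list("b[c]", "C1"),
         list("bio[c]", "C1")),
    list(list("EX_a(e)", "a[e] <=>", -10, 1000),
         list("At", "a[e] <=> a[c]", -1000, 1000),
         list("AB", "a[c] -> b[c]", 0, 1000),
         list("BIO", "b[c] -> bio[c]", 0, 1000),
         list("DM_bio", "bio[c] ->", 0, 1000)),
    "BIO")
}

# two micro-species sharing reaction R2; spA = {R1,R2}, spB = {R2,R3}
union_pair <- function() {
  spA <- build_model(
    "spA",
    list(list("a[e]", "C1"), list("a[c]", "C1"), list("bioA[c]", "C1")),
    list(list("R1", "a[e] <=>", -10, 1000),
         list("R2", "a[e] <=> a[c]", -1000, 1000),
         list("BIO_A", "a[c] -> bioA[c]", 0, 1000),
         list("DM_A", "bioA[c] ->", 0, 1000)),
    "BIO_A")
  spB <- build_model(
    "spB",
    list(list("a[e]", "C1"), list("a[c]", "C1"), list("b[c]", "C1"),
         list("bioB[c]", "C1")),
    list(list("R2", "a[e] <=> a[c]", -1000, 1000),
         list("R3", "a[c] -> b[c]", 0, 1000),
         list("BIO_B", "b[c] -> bioB[c]", 0, 1000),
         list("DM_B", "bioB[c] ->", 0, 1000)),
    "BIO_B")
  biomass_db <- structure(list(
    spA = list(species_id = "spA", reaction_id = "BIO_A",
               stoichiometry = parse_stoichiometry("a[c] -> bioA[c]"),
               biomass_metabolite = "bioA[c]", drain_id = "DM_A"),
    spB = list(species_id = "spB", reaction_id = "BIO_B",
               stoichiometry = parse_stoichiometry("b[c] -> bioB[c]"),
               biomass_metabolite = "bioB[c]", drain_id = "DM_B")),
    class = "biomass_database")
  diet <- diet_spec("pair_diet", data.frame(
    reaction_id = "R1", lower_bound = -10, upper_bound = 1000,
    stringsAsFactors = FALSE))
  list(models = list(spA = spA, spB = spB), biomass_db = biomass_db,
       diet = diet)
}

# two-species genus with a growth-limiting vitamin: metabolite M is a
# biomass byproduct of species 1 only (its maximum production equals
# s_1 at the vitamin-limited optimum of 1), W is a byproduct of both
# species (production 1 regardless of composition)
bandwidth_genus <- function() {
  shared_mets <- list(
    list("nut[e]", "C6"), list("nut[c]", "C6"), list("pre1[c]", "C3"),
    list("vit[e]", "N1"), list("vit[c]", "N1"),
    list("W[c]", "C3"), list("W[e]", "C3"))
  shared_rxns <- list(
    list("EX_nut(e)", "nut[e] <=>", -1000, 1000),
    list("NUTt", "nut[e] <=> nut[c]", -1000, 1000),
    list("NUTCLV", "nut[c] -> 2 pre1[c]", 0, 1000),
    list("EX_vit(e)", "vit[e] <=>", -1000, 1000),
    list("VITt", "vit[e] <=> vit[c]", -1000, 1000),
    list("WT", "W[c] -> W[e]", 0, 1000),
    list("EX_W(e)", "W[e] <=>", -1000, 1000))
  bio1 <- "3 pre1[c] + vit[c] -> biomass_bw1[c] + M[c] + W[c]"
  bio2 <- "2 pre1[c] + vit[c] -> biomass_bw2[c] + W[c]"
  sp1 <- build_model(
    "bw_sp1",
    c(shared_mets, list(list("M[c]", "C3"), list("M[e]", "C3"),
                        list("biomass_bw1[c]", "C3N1"))),
    c(shared_rxns,
      list(list("MT", "M[c] -> M[e]", 0, 1000),
           list("EX_M(e)", "M[e] <=>", -1000, 1000),
           list("BIO_bw1", bio1, 0, 1000),
           list("DM_bw1", "biomass_bw1[c] ->", 0, 1000))),
    "BIO_bw1")
  sp2 <- build_model(
    "bw_sp2",
    c(shared_mets, list(list("biomass_bw2[c]", "C3N1"))),
    c(shared_rxns,
      list(list("BIO_bw2", bio2, 0, 1000),
           list("DM_bw2", "biomass_bw2[c] ->", 0, 1000))),
    "BIO_bw2")
  biomass_db <- structure(list(
    bw_sp1 = list(species_id = "bw_sp1", reaction_id = "BIO_bw1",
                  stoichiometry = parse_stoichiometry(bio1),
                  biomass_metabolite = "biomass_bw1[c]",
                  drain_id = "DM_bw1"),
    bw_sp2 = list(species_id = "bw_sp2", reaction_id = "BIO_bw2",
                  stoichiometry = parse_stoichiometry(bio2),
                  biomass_metabolite = "biomass_bw2[c]",
                  drain_id = "DM_bw2")),
    class = "biomass_database")
  diet <- diet_spec("bw_diet", data.frame(
    reaction_id = c("EX_nut(e)", "EX_vit(e)"),
    lower_bound = c(-10, -1), upper_bound = c(1000, 1000),
    stringsAsFactors = FALSE))
  list(models = list(bw_sp1 = sp1, bw_sp2 = sp2),
       biomass_db = biomass_db, diet = diet)
}

# map a member model's exchange ids to the matching community lumen ids
lumen_ids_for <- function(model) {
  ex <- exchange_reactions(model)
  base <- sub("\\[e\\]$", "", unname(exchange_metabolites(model, ex)))
  stats::setNames(sprintf("EX_%s(u)", base), ex)
}
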