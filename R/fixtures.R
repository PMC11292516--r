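# Synthetic fixtures: toy genera of growth-capable species models with a
# shared reaction namespace, plus synthetic relative-abundance tables.
#
# The toy chemistry is carbon-only and balanced by construction: one
# nutrient (C6) is cleaved into C3 precursor units that flow down an
# irreversible core chain shared by every species; species differ in
# accessory interconversions, an optional alternative nutrient module,
# and species-unique secreted metabolites. Each species' biomass reaction
# consumes 2-4 precursors with integer coefficients, so species-aware and
# lumped (averaged) biomass formulations genuinely differ.

#' Generate a toy genus of species-level metabolic models
#'
#' Emulates a genus of AGORA-style reconstructions sharing one reaction
#' namespace: all species carry the core nutrient-assimilation chain;
#' accessory reactions (precursor interconversions and an alternative
#' nutrient module) are present in seeded random subsets of species; each
#' species secretes `n_unique_per_species` private metabolites and has a
#' distinct biomass reaction. Every species grows on the emitted diet.
#'
#' @param n_species Number of species (>= 1).
#' @param n_core_reactions Number of C3 precursor pools in the core chain
#'   (>= 2; precursor `pre1` feeds an irreversible chain up to
#'   `pre<n_core_reactions>`).
#' @param n_unique_per_species Secreted metabolites private to each
#'   species.
#' @param n_accessory Number of accessory precursor interconversions
#'   randomly assigned to species subsets.
#' @param genus_id Genus name used in species ids (`<genus>_sp01` ...).
#' @param seed Integer seed; all randomness is derived from it.
#' @return List with `models` (list of `metabolic_model`), `presence`
#'   (ground-truth binary reaction x species matrix over non-biomass
#'   reactions), `databases` (`$reactions`, `$biomass`), `diet`
#'   (`diet_spec`), and the flat tables `reaction_table`, `biomass_table`,
#'   `diet_table` ready to be written as TSV.
#' @export
make_toy_genus <- function(n_species = 5, n_core_reactions = 4,
                           n_unique_per_species = 1, n_accessory = 3,
                           genus_id = "Genus1", seed = 1) {
  if (n_species < 1) stop("infeasible spec: n_species must be >= 1")
  if (n_core_reactions < 2)
    stop("infeasible spec: need at least 2 core precursor pools")
  set.seed(seed)
  sample1 <- function(x) x[sample.int(length(x), 1L)]  # scalar-safe draw
  K <- n_core_reactions
  species <- sprintf("%s_sp%02d", genus_id, seq_len(n_species))
  pre <- sprintf("pre%d[c]", seq_len(K))

  met <- function(id, formula, name = id) {
    comp <- sub("^.*\\[(.*)\\]$", "\\1", id)
    data.frame(id = id, name = name, compartment = comp,
               formula = formula, charge = 0L, stringsAsFactors = FALSE)
  }
  mets <- rbind(
    met("nut[e]", "C6"), met("nut[c]", "C6"),
    met("nut2[e]", "C6"), met("nut2[c]", "C6"),
    do.call(rbind, lapply(pre, met, formula = "C3")))

  rxn <- function(id, stoich, lb, ub, subsystem) {
    list(id = id, name = id, stoichiometry = parse_stoichiometry(stoich),
         lower_bound = lb, upper_bound = ub, subsystem = subsystem,
         gene_rule = "")
  }
  core <- list(
    rxn("EX_nut(e)", "nut[e] <=>", -1000, 1000, "Exchange"),
    rxn("NUTt", "nut[e] <=> nut[c]", -1000, 1000, "Transport"),
    rxn("NUTCLV", "nut[c] -> 2 pre1[c]", 0, 1000, "Core"))
  for (j in 2:K) {
    core[[length(core) + 1L]] <-
      rxn(sprintf("PREC%d", j),
          sprintf("pre%d[c] -> pre%d[c]", j - 1L, j), 0, 1000, "Core")
  }
  core_ids <- vapply(core, `[[`, character(1), "id")

  # accessory module A: alternative nutrient, random proper subset
  alt <- list(
    rxn("EX_nut2(e)", "nut2[e] <=>", -1000, 1000, "Exchange"),
    rxn("NUT2t", "nut2[e] <=> nut2[c]", -1000, 1000, "Transport"),
    rxn("NUT2CLV", "nut2[c] -> 2 pre1[c]", 0, 1000, "Accessory"))
  alt_members <- if (n_species == 1) 1L else
    sort(sample.int(n_species, sample1(seq_len(n_species - 1L))))

  # accessory module B: reversible precursor interconversions
  acc <- list(); acc_members <- list()
  if (n_accessory > 0 && K >= 2) {
    pairs <- utils::combn(K, 2)
    pick <- sample.int(ncol(pairs), min(n_accessory, ncol(pairs)))
    for (p in pick) {
      j <- pairs[1, p]; k2 <- pairs[2, p]
      id <- sprintf("ACC_pre%d_pre%d", j, k2)
      acc[[id]] <- rxn(id, sprintf("pre%d[c] <=> pre%d[c]", j, k2),
                       -1000, 1000, "Accessory")
      acc_members[[id]] <- sort(sample.int(n_species,
                                           sample1(seq_len(n_species))))
    }
  }

  # species-unique secretion branches
  uniq <- stats::setNames(vector("list", n_species), species)
  for (i in seq_len(n_species)) {
    for (u in seq_len(n_unique_per_species)) {
      mid <- sprintf("uq_%02d_%d", i, u)
      src <- sample.int(K, 1L)
      mets <- rbind(mets, met(sprintf("%s[c]", mid), "C3"),
                    met(sprintf("%s[e]", mid), "C3"))
      uniq[[i]] <- c(uniq[[i]], list(
        rxn(sprintf("USYN_%s", mid),
            sprintf("pre%d[c] -> %s[c]", src, mid), 0, 1000, "Unique"),
        rxn(sprintf("UT_%s", mid),
            sprintf("%s[c] -> %s[e]", mid, mid), 0, 1000, "Transport"),
        rxn(sprintf("EX_%s(e)", mid),
            sprintf("%s[e] <=>", mid), -1000, 1000, "Exchange")))
    }
  }

  # species biomass: integer draw on a random 2-4 precursor subset
  bio_sets <- list(); bio_coefs <- list()
  for (i in seq_len(n_species)) {
    sz <- sample1(2:min(4, K))
    bio_sets[[i]] <- sort(sample.int(K, sz))
    bio_coefs[[i]] <- sample(1:3, sz, replace = TRUE)
  }
  if (n_species >= 2) {
    same <- all(vapply(bio_sets, function(s)
      identical(s, bio_sets[[1]]), logical(1)))
    coefs_same <- same && all(vapply(bio_coefs, function(x)
      identical(x, bio_coefs[[1]]), logical(1)))
    if (same) {
      # guarantee structurally distinct biomasses so lumped (present-only
      # averaged) and species-aware formulations cannot coincide
      s2 <- bio_sets[[2]]
      alt_pre <- setdiff(seq_len(K), s2)
      if (length(alt_pre)) bio_sets[[2]][1] <- min(alt_pre)
      else if (coefs_same) bio_coefs[[2]][1] <- bio_coefs[[2]][1] + 1L
      bio_sets[[2]] <- sort(bio_sets[[2]])
    }
  }

  models <- list()
  bio_rows <- list()
  for (i in seq_len(n_species)) {
    sp <- species[i]
    bmet <- sprintf("biomass_%s[c]", sp)
    carbons <- 3L * sum(bio_coefs[[i]])
    lhs <- paste(sprintf("%d pre%d[c]", bio_coefs[[i]], bio_sets[[i]]),
                 collapse = " + ")
    bio_eq <- sprintf("%s -> %s", lhs, bmet)
    bio_id <- sprintf("BIO_%s", sp)
    dm_id <- sprintf("DM_biomass_%s", sp)
    sp_rxns <- c(core,
                 if (i %in% alt_members) alt else list(),
                 acc[vapply(names(acc), function(a)
                   i %in% acc_members[[a]], logical(1))],
                 uniq[[i]],
                 list(rxn(bio_id, bio_eq, 0, 1000, "Biomass"),
                      rxn(dm_id, sprintf("%s ->", bmet), 0, 1000,
                          "Demand")))
    sp_mets <- rbind(mets, met(bmet, sprintf("C%d", carbons), "biomass"))
    models[[sp]] <- model_from_templates(sp, sp_mets, sp_rxns, bio_id)
    bio_rows[[sp]] <- data.frame(
      species_id = sp, reaction_id = bio_id, stoichiometry = bio_eq,
      biomass_metabolite = bmet, drain_id = dm_id,
      stringsAsFactors = FALSE)
  }

  # ground-truth presence over the union of non-biomass reactions
  all_tmpl <- c(core, alt, acc, unlist(uniq, recursive = FALSE))
  all_ids <- unique(vapply(all_tmpl, `[[`, character(1), "id"))
  presence <- matrix(0L, length(all_ids), n_species,
                     dimnames = list(all_ids, species))
  for (i in seq_len(n_species)) {
    ids_i <- c(core_ids,
               if (i %in% alt_members)
                 vapply(alt, `[[`, character(1), "id"),
               names(acc)[vapply(names(acc), function(a)
                 i %in% acc_members[[a]], logical(1))],
               vapply(uniq[[i]], `[[`, character(1), "id"))
    presence[ids_i, i] <- 1L
  }

  reaction_table <- do.call(rbind, lapply(all_tmpl, function(t)
    data.frame(id = t$id, name = t$name,
               stoichiometry = format_stoichiometry(
                 t$stoichiometry, attr(t$stoichiometry, "reversible")),
               lower_bound = t$lower_bound, upper_bound = t$upper_bound,
               subsystem = t$subsystem, stringsAsFactors = FALSE)))
  reaction_table <- reaction_table[!duplicated(reaction_table$id), ]
  biomass_table <- do.call(rbind, bio_rows)
  diet_table <- data.frame(reaction_id = c("EX_nut(e)", "EX_nut2(e)"),
                           uptake = c(10, 10), stringsAsFactors = FALSE)
  diet <- diet_spec("toy_diet",
                    data.frame(reaction_id = diet_table$reaction_id,
                               lower_bound = -diet_table$uptake,
                               upper_bound = 1000,
                               stringsAsFactors = FALSE))
  databases <- databases_from_tables(reaction_table, biomass_table)
  list(genus_id = genus_id, species = species, models = models,
       presence = presence, databases = databases, diet = diet,
       reaction_table = reaction_table, biomass_table = biomass_table,
       diet_table = diet_table)
}

# assemble a metabolic_model from reaction templates
model_from_templates <- function(id, mets, templates, objective) {
  ids <- vapply(templates, `[[`, character(1), "id")
  used <- unique(unlist(lapply(templates, function(t) names(t$stoichiometry))))
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  missing <- setdiff(used, mets$id)
  if (length(missing)) stop("metabolites without records: ",
                            paste(missing, collapse = ", "))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  S <- Matrix::sparseMatrix(
    i = match(unlist(lapply(templates, function(t) names(t$stoichiometry))),
              mets$id),
    j = rep(seq_along(templates),
            vapply(templates, function(t) length(t$stoichiometry),
                   integer(1))),
    x = unlist(lapply(templates, `[[`, "stoichiometry")),
    dims = c(nrow(mets), length(templates)))
  rxns <- data.frame(
    id = ids,
    name = vapply(templates, `[[`, character(1), "name"),
    lower_bound = vapply(templates, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(templates, `[[`, numeric(1), "upper_bound"),
    gene_rule = vapply(templates, `[[`, character(1), "gene_rule"),
    subsystem = vapply(templates, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE)
  metabolic_model(id, mets, rxns, S, objective)
}

# build database objects directly from in-memory fixture tables
databases_from_tables <- function(reaction_table, biomass_table) {
  td <- tempfile(); dir.create(td)
  rt <- file.path(td, "reactions.tsv"); bt <- file.path(td, "biomass.tsv")
  utils::write.table(reaction_table, rt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(biomass_table, bt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  on.exit(unlink(td, recursive = TRUE))
  load_databases(rt, bt)
}

#' Write toy-genus fixtures to disk
#'
#' Writes one SBML file per species plus the reaction, biomass and diet
#' TSVs into a directory.
#'
#' @param genus Result of [make_toy_genus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_genus <- function(genus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(genus$models))
    write_model(genus$models[[sp]], file.path(dir, paste0(sp, ".xml")))
  utils::write.table(genus$reaction_table, file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genus$biomass_table, file.path(dir, "biomass.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genus$diet_table, file.path(dir, "diet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Construct a relative-abundance table
#'
#' @param values Numeric matrix, samples x taxa (dimnames required).
#' @param resolution Character vector over taxa, each `"species"` or
#'   `"genus"`.
#' @return An `abundance_table`; rows are renormalized to sum to 1.
#' @export
abundance_table <- function(values, resolution) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("abundances must be nonnegative")
  resolution <- rep_len(resolution, ncol(values))
  if (!all(resolution %in% c("species", "genus")))
    stop("resolution tags must be 'species' or 'genus'")
  rs <- rowSums(values)
  if (any(rs <= 0)) stop("sample(s) with zero total abundance: ",
                         paste(rownames(values)[rs <= 0], collapse = ", "))
  values <- values / rs
  structure(list(values = values,
                 resolution = stats::setNames(resolution, colnames(values))),
            class = "abundance_table")
}

#' Simulate synthetic relative abundances
#'
#' Each sample draws exactly `k` taxa from the pool, assigns each a
#' uniform(0,1) weight, and normalizes the sample to sum to 1.
#'
#' @param n_samples Number of samples.
#' @param k Taxa per sample (`k <= length(pool)`).
#' @param pool Character vector of candidate taxa (species ids).
#' @param seed Integer seed.
#' @return An `abundance_table` (all taxa tagged `"species"`).
#' @export
make_synthetic_abundances <- function(n_samples, k, pool, seed = 1) {
  if (k > length(pool)) stop("k exceeds the taxon pool size")
  set.seed(seed)
  vals <- matrix(0, n_samples, length(pool),
                 dimnames = list(sprintf("S%03d", seq_len(n_samples)), pool))
  for (s in seq_len(n_samples)) {
    taxa <- sample(pool, k)
    vals[s, taxa] <- stats::runif(k)
  }
  abundance_table(vals, "species")
}

#' Mask a fraction of species taxa to genus level
#'
#' Emulates amplicon-style mixed resolution: a seeded random fraction of
#' the species-level taxa are re-tagged to their genus and their
#' abundances summed per genus within each sample; row sums are
#' preserved.
#'
#' @param table An `abundance_table`.
#' @param fraction Fraction of species taxa to mask (0..1).
#' @param genus_map Named character vector, species id -> genus id; must
#'   cover every species taxon.
#' @param seed Integer seed.
#' @return An `abundance_table` mixing species- and genus-level taxa.
#' @export
mask_to_genus <- function(table, fraction = 0.5, genus_map, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  sp_taxa <- names(table$resolution)[table$resolution == "species"]
  unmapped <- setdiff(sp_taxa, names(genus_map))
  if (length(unmapped)) stop("missing genus mapping for: ",
                             paste(unmapped, collapse = ", "))
  n_mask <- round(fraction * length(sp_taxa))
  if (n_mask == 0) return(table)
  set.seed(seed)
  masked <- sample(sp_taxa, n_mask)
  keep <- setdiff(colnames(table$values), masked)
  genera <- sort(unique(genus_map[masked]))
  gvals <- sapply(genera, function(g) {
    cols <- masked[genus_map[masked] == g]
    rowSums(table$values[, cols, drop = FALSE])
  })
  if (is.null(dim(gvals)))
    gvals <- matrix(gvals, ncol = length(genera),
                    dimnames = list(rownames(table$values), genera))
  vals <- cbind(table$values[, keep, drop = FALSE], gvals)
  res <- c(table$resolution[keep],
           stats::setNames(rep("genus", length(genera)), genera))
  abundance_table(vals, res[colnames(vals)])
}

#' Filter rare taxa
#'
#' Zeroes entries below the detection threshold, renormalizes each
#' sample to sum to 1, and drops taxa left at zero everywhere.
#'
#' @param table An `abundance_table`.
#' @param threshold Relative-abundance threshold (default `1e-3`).
#' @return A filtered `abundance_table`.
#' @export
filter_rare <- function(table, threshold = 1e-3) {
  stopifnot(inherits(table, "abundance_table"))
  vals <- table$values
  vals[vals < threshold] <- 0
  dead <- rowSums(vals) <= 0
  if (any(dead))
    stop("sample(s) lost all taxa at threshold ", threshold, ": ",
         paste(rownames(vals)[dead], collapse = ", "))
  keep <- colSums(vals) > 0
  abundance_table(vals[, keep, drop = FALSE], table$resolution[keep])
}

#' Write / read an abundance table
#'
#' TSV layout: columns `taxon`, `resolution`, then one column per sample.
#'
#' @param table An `abundance_table`.
#' @param path TSV path.
#' @return `path` invisibly; `read_abundances` returns the table.
#' @export
write_abundances <- function(table, path) {
  out <- data.frame(taxon = colnames(table$values),
                    resolution = unname(table$resolution),
                    t(table$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundances
#' @export
read_abundances <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  vals <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  colnames(vals) <- tab$taxon
  abundance_table(vals, tab$resolution)
}
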