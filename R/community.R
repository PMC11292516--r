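# Community model assembly.
#
# Members are compartmentalized: every internal id is prefixed with the
# member tag and each member exchange reaction is replaced by a transport
# between the member's (prefixed) extracellular metabolite and a shared,
# unprefixed lumen metabolite in compartment [u]. The community model adds
# one diet-facing exchange per lumen metabolite and a community biomass
# reaction consuming each member's biomass metabolite with its relative
# abundance as stoichiometric coefficient.

#' Compartmentalize a member model
#'
#' Prefixes all metabolites and reactions with `tag_`, replaces each
#' exchange reaction by a transport `tag_<met>[e] <-> <met>[u]` (bounds
#' -1000/1000, mgPipe convention) and leaves the lumen metabolites
#' unprefixed so that members connect through them.
#'
#' @param model A `metabolic_model`.
#' @param tag Member id used as prefix; re-tagging an already tagged
#'   model is an error.
#' @return A `metabolic_model` whose boundary is the lumen; lumen
#'   metabolite ids are recorded in attribute `"lumen_metabolites"`.
#' @export
compartmentalize_member <- function(model, tag) {
  model <- as_metabolic_model(model)
  if (!grepl("^[A-Za-z0-9_.]+$", tag)) stop("invalid member tag: ", tag)
  pre <- paste0(tag, "_")
  if (any(startsWith(model$metabolites$id, pre)) ||
      any(startsWith(model$reactions$id, pre)))
    stop("tag collision: model already carries prefix '", pre, "'")
  ex <- exchange_reactions(model)
  ex_met <- exchange_metabolites(model, ex)
  lumen_of <- function(met) sub("\\[[^]]*\\]$", "[u]", met)

  mets <- model$metabolites
  new_met_id <- paste0(pre, mets$id)
  lumen_ids <- unique(lumen_of(ex_met))
  lumen_src <- match(ex_met[!duplicated(lumen_of(ex_met))], mets$id)
  lumen_mets <- data.frame(
    id = lumen_ids,
    name = mets$name[lumen_src],
    compartment = "u",
    formula = mets$formula[lumen_src],
    charge = mets$charge[lumen_src], stringsAsFactors = FALSE)
  mets$id <- new_met_id
  mets <- rbind(mets, lumen_mets)

  tmpl <- list()
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    nz <- which(model$S[, j] != 0)
    stoich <- stats::setNames(model$S[nz, j], new_met_id[nz])
    if (rid %in% ex) {
      met_e <- paste0(pre, ex_met[[rid]])
      lum <- lumen_of(ex_met[[rid]])
      base <- sub("\\[[^]]*\\]$", "", ex_met[[rid]])
      tmpl[[length(tmpl) + 1L]] <- list(
        id = paste0(pre, "TR_", base),
        name = paste("lumen transport", base),
        stoichiometry = stats::setNames(c(-1, 1), c(met_e, lum)),
        lower_bound = -1000, upper_bound = 1000,
        gene_rule = "", subsystem = "Transport, lumen")
    } else {
      tmpl[[length(tmpl) + 1L]] <- list(
        id = paste0(pre, rid), name = model$reactions$name[j],
        stoichiometry = stoich,
        lower_bound = model$reactions$lower_bound[j],
        upper_bound = model$reactions$upper_bound[j],
        gene_rule = model$reactions$gene_rule[j],
        subsystem = model$reactions$subsystem[j])
    }
  }
  out <- model_from_templates(paste0(tag, "__member"), mets, tmpl,
                              objective = tmpl[[length(tmpl)]]$id)
  obj <- paste0(pre, model$objective)
  if (obj %in% out$reactions$id) out$objective <- obj
  attr(out, "lumen_metabolites") <- intersect(lumen_ids, out$metabolites$id)
  out
}

#' Build a lumped-biomass genus model
#'
#' Merges the member models (as [collect_unique_reactions()]) and adds a
#' single biomass reaction whose coefficient for each biomass metabolite
#' is the arithmetic mean of that metabolite's coefficients across the
#' species biomass reactions. With the default `"present_only"` mode only
#' the species containing the metabolite contribute to the mean;
#' `"zero_filled"` divides by the total species count instead. The
#' species biomass products are unified into a `lumpedBiomass[c]`
#' metabolite drained by a demand reaction.
#'
#' @param models List of species `metabolic_model`s.
#' @param biomass_db A `biomass_database`.
#' @param mode Averaging convention, `"present_only"` or `"zero_filled"`.
#' @return A `metabolic_model` with objective `lumpedBiomass`; attributes
#'   `"biomass_metabolite"` and `"drain_id"` mark the coupling points.
#' @export
build_lumped_pan_biomass <- function(models, biomass_db,
                                     mode = c("present_only",
                                              "zero_filled")) {
  mode <- match.arg(mode)
  un <- collect_unique_reactions(models, biomass_db)
  draft <- un$draft
  n <- length(un$species_list)
  sums <- numeric(0); counts <- numeric(0)
  for (sp in un$species_list) {
    b <- db_lookup(biomass_db, sp)
    st <- b$stoichiometry
    names(st)[names(st) == b$biomass_metabolite] <- "lumpedBiomass[c]"
    for (met in names(st)) {
      sums[met] <- st[[met]] + if (met %in% names(sums)) sums[[met]] else 0
      counts[met] <- 1 + if (met %in% names(counts)) counts[[met]] else 0
    }
  }
  coefs <- if (mode == "present_only") sums / counts else sums / n
  mets <- draft$metabolites
  missing <- setdiff(names(coefs), mets$id)
  for (mid in missing) {
    comp <- sub("^.*\\[(.*)\\]$", "\\1", mid)
    mets <- rbind(mets, data.frame(
      id = mid, name = if (mid == "lumpedBiomass[c]") "lumped biomass"
                       else mid,
      compartment = comp, formula = "", charge = 0L,
      stringsAsFactors = FALSE))
  }
  tmpl_old <- lapply(seq_len(nrow(draft$reactions)), function(j) {
    nz <- which(draft$S[, j] != 0)
    list(id = draft$reactions$id[j], name = draft$reactions$name[j],
         stoichiometry = stats::setNames(draft$S[nz, j],
                                         draft$metabolites$id[nz]),
         lower_bound = draft$reactions$lower_bound[j],
         upper_bound = draft$reactions$upper_bound[j],
         gene_rule = draft$reactions$gene_rule[j],
         subsystem = draft$reactions$subsystem[j])
  })
  tmpl_new <- list(
    list(id = "lumpedBiomass", name = "lumped biomass",
         stoichiometry = coefs, lower_bound = 0, upper_bound = 1000,
         gene_rule = "", subsystem = "Biomass"),
    list(id = "DM_lumpedBiomass", name = "lumped biomass drain",
         stoichiometry = c("lumpedBiomass[c]" = -1),
         lower_bound = 0, upper_bound = 1000, gene_rule = "",
         subsystem = "Demand"))
  out <- model_from_templates(paste0("lumped_", models[[1]]$id), mets,
                              c(tmpl_old, tmpl_new),
                              objective = "lumpedBiomass")
  attr(out, "biomass_metabolite") <- "lumpedBiomass[c]"
  attr(out, "drain_id") <- "DM_lumpedBiomass"
  attr(out, "species_list") <- un$species_list
  out
}

# resolve a registry entry to (plain member model, biomass metabolite,
# drain reaction id) according to the community type routing
resolve_member <- function(taxon, registry, type, biomass_db, priors) {
  if (!taxon %in% names(registry))
    stop("unresolvable taxon '", taxon, "' for community type ", type)
  src <- registry[[taxon]]
  if (inherits(src, "pan_genus_model")) {
    if (type == "gsmm")
      stop("taxon '", taxon, "' maps to a PGMM but type is 'gsmm'")
    p <- if (!is.null(priors) && taxon %in% names(priors))
      priors[[taxon]] else rep(1, length(src$species_list))
    cust <- apply_species_probabilities(src, p)
    list(model = cust$model, biomass_met = "panBiomass[c]",
         drain = cust$drain_id, source_type = "PGMM",
         source_id = src$model$id)
  } else {
    m <- as_metabolic_model(src)
    bio_met <- attr(src, "biomass_metabolite")
    drain <- attr(src, "drain_id")
    stype <- "lumped"
    if (is.null(bio_met)) {
      b <- db_lookup(biomass_db, taxon)
      bio_met <- b$biomass_metabolite
      drain <- b$drain_id
      stype <- "GSMM"
    }
    list(model = m, biomass_met = bio_met, drain = drain,
         source_type = stype, source_id = m$id)
  }
}

#' Assemble a community model from one abundance profile
#'
#' Builds a compartmentalized multi-member model of the requested type:
#' `"gsmm"` (all members species GSMMs), `"pgmm"` (genus-level members,
#' each a PGMM customized with uniform or prior within-genus species
#' probabilities), `"lumped"` (genus members with an averaged lumped
#' biomass, see [build_lumped_pan_biomass()]) or `"hybrid"`
#' (species-resolved taxa as GSMMs, genus-resolved taxa as PGMMs). The
#' community biomass reaction consumes each member's biomass metabolite
#' with its relative abundance as coefficient and is set as objective;
#' the diet is applied on the lumen exchanges.
#'
#' @param abundances Named numeric vector (taxon -> relative abundance)
#'   or an `abundance_table` together with `sample`.
#' @param registry Named list mapping each taxon to its source model: a
#'   `metabolic_model` (GSMM or lumped genus model) or a
#'   `pan_genus_model`.
#' @param type Community type: `"gsmm"`, `"pgmm"`, `"lumped"` or
#'   `"hybrid"`.
#' @param diet A `diet_spec` applied to the lumen (close_unlisted).
#' @param biomass_db `biomass_database` for species-level members.
#' @param sample Sample id when `abundances` is an `abundance_table`.
#' @param priors Optional named list taxon -> species probability weights
#'   for PGMM members.
#' @return A `community_model`.
#' @export
build_community <- function(abundances, registry, type, diet, biomass_db,
                            sample = NULL, priors = NULL) {
  type <- match.arg(type, c("gsmm", "pgmm", "lumped", "hybrid"))
  if (inherits(abundances, "abundance_table")) {
    if (is.null(sample)) stop("give `sample` with an abundance_table")
    abundances <- abundances$values[sample, ]
  }
  if (is.null(names(abundances))) stop("abundances must be named by taxon")
  if (any(abundances < 0) || sum(abundances) <= 0)
    stop("abundances not normalizable")
  taxa <- names(abundances)[abundances > 0 |
                              names(abundances) %in% names(registry)]
  abundances <- abundances[taxa] / sum(abundances[taxa])

  members <- list(); tags <- character(0)
  for (taxon in taxa) {
    res <- resolve_member(taxon, registry, type, biomass_db, priors)
    tag <- gsub("[^A-Za-z0-9_.]", "_", taxon)
    if (tag %in% tags) stop("tag collision: ", tag)
    tags <- c(tags, tag)
    m <- res$model
    if (!is.na(res$drain) && res$drain %in% m$reactions$id) {
      keep <- m$reactions$id != res$drain
      S <- m$S[, keep, drop = FALSE]
      used <- Matrix::rowSums(S != 0) > 0
      m <- metabolic_model(m$id, m$metabolites[used, , drop = FALSE],
                           m$reactions[keep, , drop = FALSE],
                           S[used, , drop = FALSE], m$objective)
    }
    cm <- compartmentalize_member(m, tag)
    members[[tag]] <- list(taxon = taxon, tag = tag, model = cm,
                           biomass_met = paste0(tag, "_", res$biomass_met),
                           source_type = res$source_type,
                           source_id = res$source_id,
                           abundance = unname(abundances[taxon]))
  }

  mets <- list(); tmpl <- list(); member_rxns <- list()
  for (mb in members) {
    mm <- mb$model
    mets[[length(mets) + 1L]] <- mm$metabolites
    ids <- mm$reactions$id
    member_rxns[[mb$tag]] <- ids
    for (j in seq_along(ids)) {
      nz <- which(mm$S[, j] != 0)
      tmpl[[length(tmpl) + 1L]] <- list(
        id = ids[j], name = mm$reactions$name[j],
        stoichiometry = stats::setNames(mm$S[nz, j], mm$metabolites$id[nz]),
        lower_bound = mm$reactions$lower_bound[j],
        upper_bound = mm$reactions$upper_bound[j],
        gene_rule = mm$reactions$gene_rule[j],
        subsystem = mm$reactions$subsystem[j])
    }
  }
  mets <- do.call(rbind, mets)
  mets <- mets[!duplicated(mets$id), , drop = FALSE]

  # one diet-facing exchange per lumen metabolite
  lumen <- mets$id[mets$compartment == "u"]
  for (lum in lumen) {
    base <- sub("\\[[^]]*\\]$", "", lum)
    tmpl[[length(tmpl) + 1L]] <- list(
      id = sprintf("EX_%s(u)", base), name = paste("lumen exchange", base),
      stoichiometry = stats::setNames(-1, lum),
      lower_bound = -1000, upper_bound = 1000, gene_rule = "",
      subsystem = "Exchange")
  }
  # community biomass
  ab <- vapply(members, `[[`, numeric(1), "abundance")
  bio_mets <- vapply(members, `[[`, character(1), "biomass_met")
  cb <- stats::setNames(-ab, bio_mets)
  cb <- cb[cb != 0]
  cb["communityBiomass[u]"] <- 1
  mets <- rbind(mets, data.frame(
    id = "communityBiomass[u]", name = "community biomass",
    compartment = "u", formula = "", charge = 0L, stringsAsFactors = FALSE))
  tmpl[[length(tmpl) + 1L]] <- list(
    id = "communityBiomass", name = "community biomass",
    stoichiometry = cb, lower_bound = 0, upper_bound = 1000,
    gene_rule = "", subsystem = "Biomass")
  tmpl[[length(tmpl) + 1L]] <- list(
    id = "EX_communityBiomass(u)", name = "community biomass drain",
    stoichiometry = c("communityBiomass[u]" = -1),
    lower_bound = 0, upper_bound = 1000, gene_rule = "",
    subsystem = "Exchange")

  model <- model_from_templates(
    paste0("community_", type,
           if (!is.null(sample)) paste0("_", sample) else ""),
    mets, tmpl, objective = "communityBiomass")
  # diet tables address single-organism exchanges, e.g. EX_glc(e); the
  # community boundary is the lumen, so retarget them to EX_glc(u)
  lum_diet <- diet
  lum_diet$bounds$reaction_id <- sub("\\(e\\)$", "(u)",
                                     lum_diet$bounds$reaction_id)
  model <- apply_diet(model, lum_diet, close_unlisted = TRUE)
  diet <- lum_diet

  comm <- structure(list(
    model = model,
    members = data.frame(
      member_id = vapply(members, `[[`, character(1), "tag"),
      taxon = vapply(members, `[[`, character(1), "taxon"),
      source_id = vapply(members, `[[`, character(1), "source_id"),
      type = vapply(members, `[[`, character(1), "source_type"),
      abundance = ab,
      biomass_met = bio_mets,
      row.names = NULL, stringsAsFactors = FALSE),
    member_reactions = member_rxns,
    lumen_compartment = "u",
    community_biomass_id = "communityBiomass",
    base_bounds = list(
      lower = stats::setNames(model$reactions$lower_bound,
                              model$reactions$id),
      upper = stats::setNames(model$reactions$upper_bound,
                              model$reactions$id)),
    diet = diet), class = "community_model")
  personalize_community(comm, abundances)
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$model$id, "\n",
      "  members: ", nrow(x$members),
      "  reactions: ", nrow(x$model$reactions),
      "  diet: ", x$diet$name, "\n", sep = "")
  invisible(x)
}

#' Personalize a community template to new abundances
#'
#' Only the community-biomass coefficients change (plus silencing of
#' zero-abundance members via zeroed bounds); the compartmentalized
#' structure is reused, so one template serves many samples.
#'
#' @param template A `community_model` containing every taxon of the
#'   sample.
#' @param abundances Named numeric vector taxon -> abundance; taxa of the
#'   template missing from `abundances` are set to 0; unknown taxa are an
#'   error. Values are renormalized to sum 1.
#' @return The personalized `community_model`.
#' @export
personalize_community <- function(template, abundances) {
  stopifnot(inherits(template, "community_model"))
  unknown <- setdiff(names(abundances), template$members$taxon)
  if (length(unknown))
    stop("taxon absent from template: ", paste(unknown, collapse = ", "))
  ab <- stats::setNames(rep(0, nrow(template$members)),
                        template$members$taxon)
  ab[names(abundances)] <- abundances
  if (any(ab < 0) || sum(ab) <= 0) stop("abundances not normalizable")
  ab <- ab / sum(ab)

  model <- template$model
  j <- match(template$community_biomass_id, model$reactions$id)
  i <- match(template$members$biomass_met, model$metabolites$id)
  S <- model$S
  S[i, j] <- -as.numeric(ab)
  model$S <- Matrix::drop0(S)

  rid <- model$reactions$id
  for (k in seq_len(nrow(template$members))) {
    ids <- template$member_reactions[[template$members$member_id[k]]]
    jj <- match(ids, rid)
    if (ab[k] == 0) {
      model$reactions$lower_bound[jj] <- 0
      model$reactions$upper_bound[jj] <- 0
    } else {
      model$reactions$lower_bound[jj] <- template$base_bounds$lower[ids]
      model$reactions$upper_bound[jj] <- template$base_bounds$upper[ids]
    }
  }
  template$model <- model
  template$members$abundance <- as.numeric(ab)
  template
}
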