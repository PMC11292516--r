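# Pan-genus metabolic model (PGMM) construction.
#
# A PGMM merges the species-level models of one genus into a single
# model: the union of all non-biomass reactions in one shared
# cytosol/extracellular pair, a per-species biomass reaction producing a
# species biomass metabolite, and a panBiomass reaction consuming those
# metabolites with the species probability vector s as stoichiometric
# coefficients (fixed-proportion semantics: at panBiomass flux v the ith
# species biomass flux is s_i * v). Species membership of every reaction
# is kept in a binary presence matrix aligned to the species list.

#' Merge the unique reactions of a genus
#'
#' Forms the union of all non-biomass reactions across the member models
#' (species biomass reactions and their drains, as recorded in the
#' biomass database, are excluded). A reaction occurring in several
#' species must have identical stoichiometry everywhere (single
#' annotation source); its merged bounds are the widest across species
#' (min of lower, max of upper) and gene rules are concatenated with a
#' species prefix.
#'
#' @param models List of `metabolic_model`s of one genus.
#' @param biomass_db A `biomass_database` covering every species.
#' @param rxn_db Optional `reaction_database`; when given, reaction names
#'   and subsystems are (re)annotated from it and every merged reaction id
#'   must be present.
#' @return List with `draft` (a `metabolic_model`; objective is a
#'   placeholder until [formulate_pan_biomass()]), `presence_matrix`
#'   (binary, reactions x species) and `species_list`.
#' @export
collect_unique_reactions <- function(models, biomass_db, rxn_db = NULL) {
  stopifnot(length(models) >= 1)
  species_list <- unname(vapply(models, function(m) m$id, character(1)))
  excluded <- unlist(lapply(biomass_db, function(b)
    c(b$reaction_id, b$drain_id)))
  excluded <- excluded[!is.na(excluded)]

  rxns <- list()          # id -> merged reaction record
  met_records <- list()   # id -> metabolite record
  presence <- list()      # id -> integer vector over species
  for (i in seq_along(models)) {
    m <- models[[i]]
    keep <- !(m$reactions$id %in% excluded)
    for (j in which(keep)) {
      rid <- m$reactions$id[j]
      col <- m$S[, j]
      nz <- which(col != 0)
      stoich <- stats::setNames(col[nz], m$metabolites$id[nz])
      stoich <- stoich[order(names(stoich))]
      rule <- m$reactions$gene_rule[j]
      if (nzchar(rule)) rule <- paste0(species_list[i], ":(", rule, ")")
      if (is.null(rxns[[rid]])) {
        rxns[[rid]] <- list(
          id = rid, name = m$reactions$name[j], stoichiometry = stoich,
          lower_bound = m$reactions$lower_bound[j],
          upper_bound = m$reactions$upper_bound[j],
          gene_rule = rule, subsystem = m$reactions$subsystem[j])
        presence[[rid]] <- integer(length(models))
      } else {
        prev <- rxns[[rid]]$stoichiometry
        if (!identical(names(prev), names(stoich)) ||
            any(abs(prev - stoich) > 1e-9))
          stop("conflict error: reaction '", rid,
               "' has differing stoichiometry across species ",
               "(models must share one annotation source)")
        rxns[[rid]]$lower_bound <- min(rxns[[rid]]$lower_bound,
                                       m$reactions$lower_bound[j])
        rxns[[rid]]$upper_bound <- max(rxns[[rid]]$upper_bound,
                                       m$reactions$upper_bound[j])
        if (nzchar(rule))
          rxns[[rid]]$gene_rule <- paste(
            c(rxns[[rid]]$gene_rule[nzchar(rxns[[rid]]$gene_rule)], rule),
            collapse = " | ")
      }
      presence[[rid]][i] <- 1L
    }
    for (k in seq_len(nrow(m$metabolites))) {
      mid <- m$metabolites$id[k]
      if (is.null(met_records[[mid]]))
        met_records[[mid]] <- m$metabolites[k, , drop = FALSE]
    }
  }
  if (length(models) >= 2) {
    shared <- vapply(presence, sum, integer(1))
    if (!any(shared >= 2L))
      stop("conflict error: models share no reactions ",
           "(disjoint reaction namespaces)")
  }
  if (!is.null(rxn_db)) {
    for (rid in names(rxns)) {
      tmpl <- db_lookup(rxn_db, rid)
      rxns[[rid]]$name <- tmpl$name
      rxns[[rid]]$subsystem <- tmpl$subsystem
    }
  }
  mets <- do.call(rbind, unname(met_records))
  draft <- model_from_templates(
    paste0("pan_", models[[1]]$id), mets, unname(rxns),
    objective = rxns[[1]]$id)
  pm <- do.call(rbind, presence[draft$reactions$id])
  dimnames(pm) <- list(draft$reactions$id, species_list)
  list(draft = draft, presence_matrix = pm, species_list = species_list)
}

#' Formulate the panBiomass objective
#'
#' Adds each species' biomass reaction (producing its species biomass
#' metabolite) and one panBiomass reaction that consumes the ith species
#' biomass metabolite with stoichiometric coefficient `s[i]` and produces
#' the `panBiomass[c]` metabolite, drained by a demand reaction. The
#' panBiomass reaction becomes the objective. With `s` absent all
#' coefficients default to `1/n` (equal species contribution).
#'
#' @param union Result of [collect_unique_reactions()] (or a compatible
#'   list with `draft`, `presence_matrix`, `species_list`).
#' @param biomass_db A `biomass_database` with an entry per species.
#' @param s Optional species probability vector (any nonnegative weights;
#'   normalized to sum to 1). Length must equal the number of species.
#' @return A `pan_genus_model`.
#' @export
formulate_pan_biomass <- function(union, biomass_db, s = NULL) {
  draft <- union$draft
  species_list <- union$species_list
  n <- length(species_list)
  if (anyDuplicated(species_list))
    stop("duplicate species ids in species_list")
  if (is.null(s)) s <- rep(1 / n, n)
  s <- make_probability_vector(s, species_list)

  mets <- draft$metabolites
  rxn_tmpl <- list()
  bio_ids <- character(n)
  bio_mets <- character(n)
  for (i in seq_len(n)) {
    b <- db_lookup(biomass_db, species_list[i])
    bio_ids[i] <- b$reaction_id
    bio_mets[i] <- b$biomass_metabolite
    for (mid in names(b$stoichiometry)) {
      if (!mid %in% mets$id) {
        comp <- sub("^.*\\[(.*)\\]$", "\\1", mid)
        mets <- rbind(mets, data.frame(
          id = mid, name = mid, compartment = comp, formula = "",
          charge = 0L, stringsAsFactors = FALSE))
      }
    }
    rxn_tmpl[[length(rxn_tmpl) + 1L]] <- list(
      id = b$reaction_id, name = paste("biomass", species_list[i]),
      stoichiometry = b$stoichiometry, lower_bound = 0,
      upper_bound = 1000, gene_rule = "", subsystem = "Biomass")
  }
  pan_stoich <- stats::setNames(-s, bio_mets)
  pan_stoich <- pan_stoich[pan_stoich != 0]
  pan_stoich["panBiomass[c]"] <- 1
  mets <- rbind(mets, data.frame(
    id = "panBiomass[c]", name = "pan-genus biomass",
    compartment = "c", formula = "", charge = 0L,
    stringsAsFactors = FALSE))
  rxn_tmpl[[length(rxn_tmpl) + 1L]] <- list(
    id = "panBiomass", name = "panBiomass",
    stoichiometry = pan_stoich, lower_bound = 0, upper_bound = 1000,
    gene_rule = "", subsystem = "Biomass")
  rxn_tmpl[[length(rxn_tmpl) + 1L]] <- list(
    id = "DM_panBiomass", name = "panBiomass drain",
    stoichiometry = c("panBiomass[c]" = -1), lower_bound = 0,
    upper_bound = 1000, gene_rule = "", subsystem = "Demand")

  old <- draft
  tmpl_old <- lapply(seq_len(nrow(old$reactions)), function(j) {
    nz <- which(old$S[, j] != 0)
    list(id = old$reactions$id[j], name = old$reactions$name[j],
         stoichiometry = stats::setNames(old$S[nz, j],
                                         old$metabolites$id[nz]),
         lower_bound = old$reactions$lower_bound[j],
         upper_bound = old$reactions$upper_bound[j],
         gene_rule = old$reactions$gene_rule[j],
         subsystem = old$reactions$subsystem[j])
  })
  model <- model_from_templates(old$id, mets, c(tmpl_old, rxn_tmpl),
                                objective = "panBiomass")

  extra <- rbind(
    matrix(diag(n)[seq_len(n), , drop = FALSE], n, n,
           dimnames = list(bio_ids, species_list)),
    matrix(1L, 2, n,
           dimnames = list(c("panBiomass", "DM_panBiomass"),
                           species_list)))
  presence <- rbind(union$presence_matrix, extra)
  presence <- presence[model$reactions$id, , drop = FALSE]

  pgmm <- structure(list(
    model = model,
    species_list = species_list,
    presence_matrix = presence,
    species_biomass_ids = stats::setNames(bio_ids, species_list),
    species_biomass_mets = stats::setNames(bio_mets, species_list),
    pan_biomass_id = "panBiomass",
    drain_id = "DM_panBiomass",
    current_probabilities = s,
    merged_bounds = list(
      lower = stats::setNames(model$reactions$lower_bound,
                              model$reactions$id),
      upper = stats::setNames(model$reactions$upper_bound,
                              model$reactions$id))),
    class = "pan_genus_model")
  validate_pgmm(pgmm)
  pgmm
}

#' Validate a pan-genus model
#'
#' Checks the PGMM invariants: binary presence matrix aligned to the
#' species list with no empty rows, species biomass rows equal to the
#' species indicator, and the panBiomass reaction set as objective.
#'
#' @param pgmm A `pan_genus_model`.
#' @return The object, invisibly; errors on violation.
#' @export
validate_pgmm <- function(pgmm) {
  stopifnot(inherits(pgmm, "pan_genus_model"))
  validate_model(pgmm$model)
  pm <- pgmm$presence_matrix
  if (!all(pm %in% c(0L, 1L))) stop("presence matrix must be binary")
  if (!identical(colnames(pm), pgmm$species_list))
    stop("presence matrix columns must match species_list")
  if (!identical(rownames(pm), pgmm$model$reactions$id))
    stop("presence matrix rows must match model reactions")
  if (any(rowSums(pm) < 1))
    stop("presence matrix has empty rows: ",
         paste(rownames(pm)[rowSums(pm) < 1], collapse = ", "))
  for (i in seq_along(pgmm$species_list)) {
    row <- pm[pgmm$species_biomass_ids[i], ]
    if (!all(row == as.integer(seq_along(row) == i)))
      stop("biomass presence row of ", pgmm$species_list[i],
           " is not the species indicator")
  }
  if (!identical(pgmm$model$objective, pgmm$pan_biomass_id))
    stop("panBiomass must be the objective")
  invisible(pgmm)
}

#' @export
print.pan_genus_model <- function(x, ...) {
  cat("<pan_genus_model> ", x$model$id, "\n",
      "  species (n=", length(x$species_list), "): ",
      paste(utils::head(x$species_list, 4), collapse = ", "),
      if (length(x$species_list) > 4) ", ..." else "", "\n",
      "  reactions: ", nrow(x$model$reactions),
      "  objective: ", x$pan_biomass_id, "\n", sep = "")
  invisible(x)
}

#' Optimize growth under a medium
#'
#' Applies the diet to a copy of the model and maximizes the biomass
#' objective.
#'
#' @param model A `metabolic_model`, `pan_genus_model` or
#'   `community_model`.
#' @param media A `diet_spec`, or `NULL` to use current bounds.
#' @param close_unlisted Passed to [apply_diet()].
#' @return Optimal objective flux (numeric); infeasible models are an
#'   error carrying the solver status.
#' @export
validate_growth <- function(model, media = NULL, close_unlisted = TRUE) {
  m <- as_metabolic_model(model)
  if (!is.null(media)) m <- apply_diet(m, media, close_unlisted)
  res <- fba(m)
  if (res$status != "optimal")
    stop("growth check failed: solver status '", res$status, "'")
  res$objective_value
}

#' Remove duplicate and futile-cycle reactions
#'
#' Exact duplicate reactions (identical stoichiometry, or sign-flipped
#' with correspondingly flipped bounds) are collapsed to one survivor
#' whose presence row is the OR of the duplicates and whose bounds cover
#' the union. Futile-cycle candidates are reactions that still carry a
#' nonzero FVA flux range when every uptake is closed; they are removed
#' greedily (descending closed-medium range, ties by id) and each removal
#' is rolled back if the biomass optimum on `media` drops by more than
#' `growth_tol` (relative).
#'
#' @param pgmm A `pan_genus_model` that grows on `media`.
#' @param media A `diet_spec`.
#' @param growth_tol Relative growth tolerance (default `1e-6`).
#' @param zero_tol Absolute flux threshold for "nonzero range".
#' @return The pruned `pan_genus_model`; removed reaction ids in
#'   attribute `"removed"`.
#' @export
prune_duplicates_and_futile <- function(pgmm, media, growth_tol = 1e-6,
                                        zero_tol = 1e-6) {
  stopifnot(inherits(pgmm, "pan_genus_model"))
  machinery <- c(pgmm$species_biomass_ids, pgmm$pan_biomass_id,
                 pgmm$drain_id)
  opt0 <- validate_growth(pgmm, media)
  if (opt0 <= zero_tol)
    stop("model does not grow on the given media (optimum ", opt0, ")")
  removed <- character(0)

  # -- duplicate collapse ----------------------------------------------
  m <- pgmm$model
  keys <- vapply(seq_len(nrow(m$reactions)), function(j) {
    nz <- which(m$S[, j] != 0)
    v <- m$S[nz, j]
    ids <- m$metabolites$id[nz]
    o <- order(ids)
    v <- v[o]; ids <- ids[o]
    flip <- v[1] < 0
    if (flip) v <- -v
    paste0(if (flip) "-" else "+", "|",
           paste(ids, sprintf("%.12g", v), sep = ":", collapse = ";"))
  }, character(1))
  base_key <- sub("^[+-]\\|", "", keys)
  flipped <- startsWith(keys, "-")
  cand <- !(m$reactions$id %in% machinery)
  groups <- split(which(cand), base_key[cand])
  drop_idx <- integer(0)
  for (g in groups) {
    if (length(g) < 2L) next
    g <- g[order(m$reactions$id[g])]
    surv <- g[1]
    for (d in g[-1]) {
      lb <- m$reactions$lower_bound[d]; ub <- m$reactions$upper_bound[d]
      if (flipped[d] != flipped[surv]) { tmp <- lb; lb <- -ub; ub <- -tmp }
      m$reactions$lower_bound[surv] <- min(m$reactions$lower_bound[surv], lb)
      m$reactions$upper_bound[surv] <- max(m$reactions$upper_bound[surv], ub)
      pgmm$presence_matrix[surv, ] <-
        pmax(pgmm$presence_matrix[surv, ], pgmm$presence_matrix[d, ])
      drop_idx <- c(drop_idx, d)
    }
  }
  if (length(drop_idx)) {
    removed <- c(removed, m$reactions$id[drop_idx])
    pgmm <- pgmm_drop_reactions(pgmm, m, drop_idx)
  } else {
    pgmm$model <- m
    pgmm <- pgmm_sync_bounds(pgmm)
  }

  # -- futile cycles: flux ranges with all uptakes closed ---------------
  closed <- set_bounds(pgmm$model, exchange_reactions(pgmm$model), lower = 0)
  scan_ids <- setdiff(closed$reactions$id,
                      c(machinery, exchange_reactions(closed)))
  if (length(scan_ids)) {
    rng <- fva(closed, scan_ids, fraction_of_optimum = 0)
    span <- rng$max_flux - rng$min_flux
    hit <- span > zero_tol
    order_idx <- order(-span[hit], rng$reaction_id[hit])
    for (rid in rng$reaction_id[hit][order_idx]) {
      j <- match(rid, pgmm$model$reactions$id)
      if (is.na(j)) next
      trial <- pgmm_drop_reactions(pgmm, pgmm$model, j)
      opt <- tryCatch(validate_growth(trial, media),
                      error = function(e) -Inf)
      if (abs(opt - opt0) / max(abs(opt0), 1e-12) < growth_tol) {
        pgmm <- trial
        removed <- c(removed, rid)
      }
    }
  }
  validate_pgmm(pgmm)
  attr(pgmm, "removed") <- removed
  pgmm
}

# drop reaction columns (and orphaned metabolites) from a PGMM, keeping
# presence matrix and merged-bound snapshots aligned
pgmm_drop_reactions <- function(pgmm, model, drop_idx) {
  keep <- setdiff(seq_len(nrow(model$reactions)), drop_idx)
  S <- model$S[, keep, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  model2 <- metabolic_model(model$id,
                            model$metabolites[used, , drop = FALSE],
                            model$reactions[keep, , drop = FALSE],
                            S[used, , drop = FALSE], model$objective)
  pgmm$model <- model2
  pgmm$presence_matrix <-
    pgmm$presence_matrix[model2$reactions$id, , drop = FALSE]
  pgmm_sync_bounds(pgmm)
}

pgmm_sync_bounds <- function(pgmm) {
  pgmm$merged_bounds <- list(
    lower = stats::setNames(pgmm$model$reactions$lower_bound,
                            pgmm$model$reactions$id),
    upper = stats::setNames(pgmm$model$reactions$upper_bound,
                            pgmm$model$reactions$id))
  pgmm
}

#' Build a pan-genus metabolic model
#'
#' Orchestrates the full reconstruction: merge the unique reactions of
#' the member models, formulate the panBiomass objective, optionally
#' prune duplicates and futile cycles, and verify growth on the medium.
#'
#' @param models List of species `metabolic_model`s.
#' @param biomass_db A `biomass_database`.
#' @param media A `diet_spec` used for pruning and the growth check
#'   (`NULL` skips both).
#' @param s Optional species probability vector; default equal (`1/n`).
#' @param rxn_db Optional `reaction_database` for annotation.
#' @param prune Run [prune_duplicates_and_futile()]?
#' @param growth_tol Relative growth tolerance.
#' @return A `pan_genus_model`; the growth optimum on `media` is stored
#'   in attribute `"growth"`.
#' @export
build_pgmm <- function(models, biomass_db, media = NULL, s = NULL,
                       rxn_db = NULL, prune = TRUE, growth_tol = 1e-6) {
  un <- collect_unique_reactions(models, biomass_db, rxn_db)
  pgmm <- formulate_pan_biomass(un, biomass_db, s)
  if (!is.null(media)) {
    if (prune)
      pgmm <- prune_duplicates_and_futile(pgmm, media,
                                          growth_tol = growth_tol)
    attr(pgmm, "growth") <- validate_growth(pgmm, media)
  }
  pgmm
}
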