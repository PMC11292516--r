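# Customizing a PGMM to a species composition.
#
# Reactions are never deleted: a reaction whose presence-weighted
# probability (presence matrix times species probability vector) is zero
# is silenced by setting both bounds to zero, and the merged bounds are
# restored when the composition changes back. The panBiomass reactant
# coefficients are rewritten to the probability vector, so composition
# affects both network structure and the biomass objective.

#' Build a species probability vector
#'
#' Normalizes nonnegative weights to sum to 1 (the `s_i` coefficients of
#' the panBiomass formulation).
#'
#' @param weights Nonnegative numeric weights, not all zero. May be named
#'   by species id.
#' @param species Optional species ordering; named weights are reordered
#'   to it (missing species get 0), unnamed weights must match its
#'   length.
#' @return Named (when `species` given) numeric vector summing to 1,
#'   class `species_probability_vector`.
#' @export
make_probability_vector <- function(weights, species = NULL) {
  if (length(weights) < 1) stop("need at least one weight")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  if (!is.null(species)) {
    if (!is.null(names(weights))) {
      unknown <- setdiff(names(weights), species)
      if (length(unknown)) stop("unknown species: ",
                                paste(unknown, collapse = ", "))
      w <- stats::setNames(rep(0, length(species)), species)
      w[names(weights)] <- weights
      weights <- w
    } else if (length(weights) != length(species)) {
      stop("dimension error: ", length(weights), " weights for ",
           length(species), " species")
    } else names(weights) <- species
  }
  structure(weights / sum(weights), class = "species_probability_vector")
}

#' Apply a species probability vector to a PGMM
#'
#' Silences every reaction whose presence-weighted probability
#' `(presence_matrix %*% p)` is zero (both bounds set to 0; strict
#' `> 0` activation, no epsilon flooring), restores merged bounds for
#' active reactions, and rewrites the panBiomass reactant coefficients to
#' `p`. Idempotent for fixed `p`, and fully reversible: re-applying a
#' permissive vector restores the as-built model.
#'
#' @param pgmm A `pan_genus_model`.
#' @param p Species probability vector (normalized internally).
#' @return The customized `pan_genus_model`.
#' @export
apply_species_probabilities <- function(pgmm, p) {
  stopifnot(inherits(pgmm, "pan_genus_model"))
  p <- make_probability_vector(unclass(p), pgmm$species_list)
  activity <- as.numeric(pgmm$presence_matrix %*% p)
  active <- activity > 0
  rid <- pgmm$model$reactions$id
  pgmm$model$reactions$lower_bound <-
    ifelse(active, pgmm$merged_bounds$lower[rid], 0)
  pgmm$model$reactions$upper_bound <-
    ifelse(active, pgmm$merged_bounds$upper[rid], 0)

  j <- match(pgmm$pan_biomass_id, rid)
  i_bio <- match(pgmm$species_biomass_mets, pgmm$model$metabolites$id)
  S <- pgmm$model$S
  S[i_bio, j] <- -as.numeric(p)
  pgmm$model$S <- Matrix::drop0(S)
  pgmm$current_probabilities <- p
  pgmm
}

#' Extract one species' model from a PGMM
#'
#' Equivalent to applying the indicator probability vector of the
#' species: every reaction absent from it is silenced and panBiomass
#' collapses to that species' biomass (coefficient 1), so the objective
#' optimum and exchange flux variability match the source GSMM.
#'
#' @param pgmm A `pan_genus_model`.
#' @param species_id A member of `pgmm$species_list`.
#' @return A `metabolic_model` view of the species.
#' @export
extract_species_model <- function(pgmm, species_id) {
  stopifnot(inherits(pgmm, "pan_genus_model"))
  if (!species_id %in% pgmm$species_list)
    stop("unknown species id '", species_id, "'")
  e <- as.numeric(pgmm$species_list == species_id)
  out <- apply_species_probabilities(pgmm, e)
  m <- out$model
  m$id <- paste0(pgmm$model$id, "_", species_id)
  m
}
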