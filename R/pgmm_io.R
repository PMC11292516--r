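# PGMM persistence: SBML for the stoichiometric part plus a JSON sidecar
# for the species-aware fields (species list, presence matrix, biomass
# bookkeeping, current probabilities) that SBML cannot hold natively.

#' Write / read a pan-genus model
#'
#' `write_pgmm` writes `<path>` as SBML and `<path stem>.json` carrying
#' `species_list`, the presence matrix, biomass reaction/metabolite maps,
#' current probabilities and the merged bounds. `read_pgmm` reassembles
#' the `pan_genus_model` from the pair.
#'
#' @param pgmm A `pan_genus_model`.
#' @param path SBML output path (`.xml`); the sidecar replaces the
#'   extension with `.json`.
#' @return `write_pgmm`: `path`, invisibly. `read_pgmm`: the model.
#' @export
write_pgmm <- function(pgmm, path) {
  validate_pgmm(pgmm)
  write_model(pgmm$model, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  payload <- list(
    species_list = pgmm$species_list,
    reaction_ids = rownames(pgmm$presence_matrix),
    presence_matrix = unname(lapply(seq_len(nrow(pgmm$presence_matrix)),
                                    function(i)
                                      as.integer(pgmm$presence_matrix[i, ]))),
    species_biomass_ids = as.list(pgmm$species_biomass_ids),
    species_biomass_mets = as.list(pgmm$species_biomass_mets),
    pan_biomass_id = pgmm$pan_biomass_id,
    drain_id = pgmm$drain_id,
    current_probabilities = as.numeric(pgmm$current_probabilities),
    merged_bounds = list(
      lower = unname(pgmm$merged_bounds$lower),
      upper = unname(pgmm$merged_bounds$upper)))
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pgmm
#' @export
read_pgmm <- function(path) {
  model <- read_model(path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("missing PGMM sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pm <- meta$presence_matrix
  if (!is.matrix(pm)) pm <- do.call(rbind, pm)
  pm <- matrix(as.integer(pm), nrow = length(meta$reaction_ids),
               dimnames = list(meta$reaction_ids, meta$species_list))
  pm <- pm[model$reactions$id, , drop = FALSE]
  pgmm <- structure(list(
    model = model,
    species_list = meta$species_list,
    presence_matrix = pm,
    species_biomass_ids = stats::setNames(
      unlist(meta$species_biomass_ids)[meta$species_list],
      meta$species_list),
    species_biomass_mets = stats::setNames(
      unlist(meta$species_biomass_mets)[meta$species_list],
      meta$species_list),
    pan_biomass_id = meta$pan_biomass_id,
    drain_id = meta$drain_id,
    current_probabilities = make_probability_vector(
      meta$current_probabilities, meta$species_list),
    merged_bounds = list(
      lower = stats::setNames(meta$merged_bounds$lower,
                              meta$reaction_ids)[model$reactions$id],
      upper = stats::setNames(meta$merged_bounds$upper,
                              meta$reaction_ids)[model$reactions$id])),
    class = "pan_genus_model")
  validate_pgmm(pgmm)
  pgmm
}
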