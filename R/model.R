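#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric model with flux
#' bounds and a biomass objective, the in-memory form of a genome-scale
#' metabolic model (GSMM). Stoichiometry is held as a sparse metabolite x
#' reaction matrix; metabolite and reaction annotations live in plain
#' data frames, so the object is cheap to copy and easy to inspect.
#'
#' @param id Model identifier (string).
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`. Ids follow the VMH bracket convention, e.g.
#'   `"glc_D[e]"`; `compartment` is the tag inside the brackets.
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`. Bounds are fluxes in
#'   mmol/gDW/h; negative flux through an exchange reaction is uptake,
#'   positive is secretion.
#' @param S Stoichiometric matrix (metabolites x reactions), any matrix
#'   coercible to `Matrix::dgCMatrix`. Row/column order must match
#'   `metabolites$id` / `reactions$id`.
#' @param objective Reaction id of the objective (usually biomass).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S, objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "compartment", "formula")) {
    if (is.null(metabolites[[col]]))
      metabolites[[col]] <- rep("", nrow(metabolites))
  }
  if (is.null(metabolites$charge))
    metabolites$charge <- rep(0L, nrow(metabolites))
  for (col in c("name", "gene_rule", "subsystem")) {
    if (is.null(reactions[[col]]))
      reactions[[col]] <- rep("", nrow(reactions))
  }
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         S = S, objective = objective),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique reaction and metabolite ids,
#' matching stoichiometry dimensions, `lower_bound <= upper_bound`
#' everywhere, every reaction carrying at least one finite, nonzero
#' stoichiometric coefficient, and the objective id present.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(rxn_ids))
    stop("integrity error: duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  if (anyDuplicated(met_ids))
    stop("integrity error: duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (!all(dim(model$S) == c(length(met_ids), length(rxn_ids))))
    stop("integrity error: stoichiometric matrix dimensions do not match")
  if (nrow(model$reactions) == 0L)
    stop("degenerate model: no reactions")
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad))
    stop("integrity error: lower_bound > upper_bound for: ",
         paste(rxn_ids[bad], collapse = ", "))
  if (!all(is.finite(model$S@x)))
    stop("integrity error: non-finite stoichiometric coefficients")
  empty <- Matrix::colSums(model$S != 0) == 0
  if (any(empty))
    stop("integrity error: reactions with empty stoichiometry: ",
         paste(rxn_ids[empty], collapse = ", "))
  if (!model$objective %in% rxn_ids)
    stop("integrity error: objective reaction '", model$objective,
         "' not in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  exchanges: ", length(exchange_reactions(x)), "\n",
      "  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

# compartments treated as outside-facing when identifying exchanges:
# 'e' (extracellular, single organism) and 'u' (shared community lumen)
EXTRACELLULAR_TAGS <- c("e", "u")

#' Identify exchange reactions
#'
#' Exchange reactions are boundary reactions with single-metabolite
#' stoichiometry whose metabolite sits in an outside-facing compartment
#' (`e`, or the community lumen `u`). Negative flux is uptake, positive is
#' secretion.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$S != 0)
  single <- which(nz == 1L)
  if (length(single) == 0L) return(character(0))
  comp <- model$metabolites$compartment
  keep <- vapply(single, function(j) {
    i <- which(model$S[, j] != 0)
    comp[i] %in% EXTRACELLULAR_TAGS
  }, logical(1))
  model$reactions$id[single[keep]]
}

#' Map exchange reactions to their metabolites
#'
#' @param model A `metabolic_model`.
#' @param rxn_ids Exchange reaction ids; defaults to all exchanges.
#' @return Named character vector, reaction id -> metabolite id.
#' @export
exchange_metabolites <- function(model, rxn_ids = exchange_reactions(model)) {
  j <- match(rxn_ids, model$reactions$id)
  if (anyNA(j)) stop("unknown reaction id(s): ",
                     paste(rxn_ids[is.na(j)], collapse = ", "))
  met <- vapply(j, function(jj) {
    model$metabolites$id[which(model$S[, jj] != 0)[1]]
  }, character(1))
  stats::setNames(met, rxn_ids)
}

#' Set flux bounds on named reactions
#'
#' @param model A `metabolic_model`.
#' @param rxn_ids Reaction ids.
#' @param lower,upper Numeric vectors (recycled) of new bounds; `NA` leaves
#'   the existing bound untouched.
#' @return The modified model.
#' @export
set_bounds <- function(model, rxn_ids, lower = NA, upper = NA) {
  j <- match(rxn_ids, model$reactions$id)
  if (anyNA(j)) stop("unknown reaction id(s): ",
                     paste(rxn_ids[is.na(j)], collapse = ", "))
  lower <- rep_len(lower, length(j))
  upper <- rep_len(upper, length(j))
  keep <- !is.na(lower)
  model$reactions$lower_bound[j[keep]] <- lower[keep]
  keep <- !is.na(upper)
  model$reactions$upper_bound[j[keep]] <- upper[keep]
  model
}

#' Check elemental balance of internal reactions
#'
#' Parses metabolite formulas (`C6H12O6` style) and verifies that every
#' non-exchange reaction conserves each element. Boundary reactions
#' (exchanges, sinks and demands: single-metabolite stoichiometry) and any
#' reaction id listed in `skip` are excluded — biomass assembly reactions
#' are conventionally unbalanced.
#'
#' @param model A `metabolic_model`.
#' @param skip Reaction ids to exclude from the check.
#' @param tol Imbalance tolerance per element.
#' @return Logical vector named by the checked reaction ids.
#' @export
check_mass_balance <- function(model, skip = character(0), tol = 1e-9) {
  counts <- parse_formulas(model$metabolites$formula)
  nz <- Matrix::colSums(model$S != 0)
  check <- setdiff(model$reactions$id[nz > 1L], skip)
  res <- vapply(check, function(r) {
    j <- match(r, model$reactions$id)
    i <- which(model$S[, j] != 0)
    bal <- colSums(counts[i, , drop = FALSE] * model$S[i, j])
    all(abs(bal) <= tol)
  }, logical(1))
  res
}

# formula strings -> matrix of element counts (rows = metabolites)
parse_formulas <- function(formulas) {
  parsed <- lapply(formulas, function(f) {
    if (is.na(f) || f == "") return(numeric(0))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    el <- sub("[0-9]*$", "", toks)
    n <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
    n[is.na(n)] <- 1
    tapply(n, el, sum)
  })
  els <- sort(unique(unlist(lapply(parsed, names))))
  out <- matrix(0, length(formulas), length(els),
                dimnames = list(NULL, els))
  for (i in seq_along(parsed)) out[i, names(parsed[[i]])] <- parsed[[i]]
  out
}
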