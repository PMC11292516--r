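# Evaluation layer on top of FVA: net exchange potential, distance
# metrics between maximum-flux profiles, the significant-flux fraction,
# the flux-bandwidth landscape over sampled species compositions, and
# UPGMA similarity trees.

#' Net exchange flux
#'
#' The net production/consumption potential of each exchange metabolite:
#' the sum of its secretion potential (FVA maximum) and uptake potential
#' (FVA minimum, negative for uptake).
#'
#' @param res An `fva_result` over exchange reactions.
#' @param model Optional model used to label results by metabolite id
#'   instead of reaction id.
#' @return Named numeric vector of net fluxes.
#' @export
net_exchange_flux <- function(res, model = NULL) {
  net <- res$max_flux + res$min_flux
  names(net) <- if (!is.null(model))
    unname(exchange_metabolites(as_metabolic_model(model),
                                res$reaction_id))
  else res$reaction_id
  net
}

check_aligned <- function(a, b) {
  if (length(a) != length(b))
    stop("misaligned vectors: lengths ", length(a), " vs ", length(b))
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop("misaligned vectors: names differ")
}

#' Jaccard distance between activity profiles
#'
#' Qualitative variation between two flux profiles: one minus the
#' Jaccard index of their active sets, where an index is active when
#' `|flux| > tol`. Two empty sets have distance 0.
#'
#' @param a,b Aligned numeric flux vectors (e.g. FVA maxima).
#' @param tol Zero-activity tolerance.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b, tol = 1e-6) {
  check_aligned(a, b)
  A <- abs(a) > tol; B <- abs(b) > tol
  uni <- sum(A | B)
  if (uni == 0) return(0)
  1 - sum(A & B) / uni
}

#' Normalized Euclidean distance
#'
#' Quantitative variation between two flux profiles: the Euclidean
#' distance divided by a normalization constant, conventionally the
#' maximum distance observed across the comparison batch.
#'
#' @param a,b Aligned numeric flux vectors.
#' @param norm_constant Positive scalar divisor.
#' @return Nonnegative real.
#' @export
normalized_euclidean <- function(a, b, norm_constant) {
  check_aligned(a, b)
  if (!is.numeric(norm_constant) || norm_constant <= 0)
    stop("norm_constant must be > 0")
  sqrt(sum((a - b)^2)) / norm_constant
}

#' Fraction of significantly different fluxes
#'
#' The fraction of compared indices whose relative flux difference
#' `|a - b| / max(|a|, |b|, eps)` exceeds `threshold` (default 10%).
#' Indices where both fluxes are inactive (`<= tol`) are excluded from
#' the comparison.
#'
#' @param a,b Aligned numeric flux vectors.
#' @param threshold Relative difference threshold (default 0.10).
#' @param tol Zero-activity tolerance for the exclusion rule.
#' @param eps Denominator floor.
#' @return Fraction in `[0, 1]`; 0 when nothing is comparable.
#' @export
significant_flux_fraction <- function(a, b, threshold = 0.10,
                                      tol = 1e-6, eps = 1e-9) {
  check_aligned(a, b)
  use <- !(abs(a) <= tol & abs(b) <= tol)
  if (!any(use)) return(0)
  rel <- abs(a[use] - b[use]) / pmax(abs(a[use]), abs(b[use]), eps)
  mean(rel > threshold)
}

#' Classify flux bandwidth
#'
#' The four regulation categories of the flux-bandwidth landscape:
#' `no_production` when both the average maximum flux and the flux range
#' are zero; `tightly_regulated` when the flux range is within 5%;
#' `low_variability` between 5% and `low_upper_pct`; `high_variability`
#' above 50%. With the default `low_upper_pct = 50` the categories are
#' exhaustive; setting 25 reproduces the verbatim band limits and labels
#' ranges in (25, 50] as `NA`.
#'
#' @param average_max_flux Mean FVA maximum across compositions.
#' @param range_pct Normalized flux range, percent.
#' @param tol Zero tolerance.
#' @param tight_pct,low_upper_pct,high_pct Band limits in percent.
#' @return Character vector of categories.
#' @export
categorize_bandwidth <- function(average_max_flux, range_pct,
                                 tol = 1e-6, tight_pct = 5,
                                 low_upper_pct = 50, high_pct = 50) {
  stopifnot(length(average_max_flux) == length(range_pct))
  out <- rep(NA_character_, length(range_pct))
  no_prod <- abs(average_max_flux) <= tol & range_pct <= tol
  out[no_prod] <- "no_production"
  tight <- !no_prod & range_pct <= tight_pct
  out[tight] <- "tightly_regulated"
  low <- !no_prod & !tight & range_pct <= low_upper_pct
  out[low] <- "low_variability"
  high <- !no_prod & !tight & range_pct > high_pct
  out[high] <- "high_variability"
  out
}

#' Flux-bandwidth landscape of a genus
#'
#' Samples `n_combinations` random species compositions (uniform(0,1)
#' weights per species, normalized to sum 1), customizes the PGMM to
#' each, runs exchange FVA under each diet, and aggregates per exchange
#' metabolite the average maximum flux, the flux range (highest minus
#' lowest maximum across compositions), the normalized range in percent
#' (`100 * range / max(|highest maximum|, eps)`), and the regulation
#' category.
#'
#' @param pgmm A `pan_genus_model`.
#' @param diets List of `diet_spec`s (or a single one).
#' @param n_combinations Number of sampled compositions (>= 2).
#' @param seed Integer seed for the composition draws.
#' @param reaction_ids Exchange reactions to profile; default all
#'   exchanges of the PGMM.
#' @param fraction_of_optimum Passed to [fva()].
#' @param eps Denominator floor for the percentage normalization.
#' @return Named list (one `bandwidth_table` data frame per diet) with
#'   columns `metabolite`, `reaction_id`, `average_max_flux`,
#'   `flux_range`, `range_pct`, `category`; infeasible compositions are
#'   skipped and counted in attribute `"n_infeasible"`.
#' @export
bandwidth_profile <- function(pgmm, diets, n_combinations = 120, seed = 1,
                              reaction_ids = NULL,
                              fraction_of_optimum = 0.9999, eps = 1e-9) {
  stopifnot(inherits(pgmm, "pan_genus_model"), n_combinations >= 2)
  if (inherits(diets, "diet_spec")) diets <- list(diets)
  if (is.null(names(diets)))
    names(diets) <- vapply(diets, `[[`, character(1), "name")
  if (is.null(reaction_ids))
    reaction_ids <- exchange_reactions(pgmm$model)
  n_sp <- length(pgmm$species_list)
  set.seed(seed)
  probs <- lapply(seq_len(n_combinations), function(i)
    stats::runif(n_sp))
  out <- list()
  for (dn in names(diets)) {
    maxima <- matrix(NA_real_, n_combinations, length(reaction_ids),
                     dimnames = list(NULL, reaction_ids))
    n_bad <- 0L
    for (i in seq_len(n_combinations)) {
      cust <- apply_species_probabilities(pgmm, probs[[i]])
      m <- apply_diet(cust$model, diets[[dn]], close_unlisted = TRUE)
      res <- tryCatch(fva(m, reaction_ids, fraction_of_optimum),
                      error = function(e) NULL)
      if (is.null(res)) { n_bad <- n_bad + 1L; next }
      maxima[i, res$reaction_id] <- res$max_flux
    }
    ok <- stats::complete.cases(maxima)
    if (sum(ok) < 2) stop("fewer than 2 feasible compositions under diet ",
                          dn)
    mx <- maxima[ok, , drop = FALSE]
    avg <- colMeans(mx)
    hi <- apply(mx, 2, max); lo <- apply(mx, 2, min)
    rng <- hi - lo
    pct <- 100 * rng / pmax(abs(hi), eps)
    tab <- data.frame(
      metabolite = unname(exchange_metabolites(pgmm$model, reaction_ids)),
      reaction_id = reaction_ids,
      average_max_flux = avg, flux_range = rng, range_pct = pct,
      category = categorize_bandwidth(avg, pct),
      row.names = NULL, stringsAsFactors = FALSE)
    class(tab) <- c("bandwidth_table", "data.frame")
    attr(tab, "n_infeasible") <- n_bad
    attr(tab, "n_used") <- sum(ok)
    out[[dn]] <- tab
  }
  out
}

#' UPGMA similarity tree
#'
#' Builds a pairwise distance matrix over entities (Jaccard for binary
#' feature matrices such as reaction or metabolite presence; Hamming,
#' i.e. fraction of mismatching features, for categorical matrices such
#' as bandwidth categories), clusters with UPGMA (average linkage) and
#' returns the dendrogram in Newick format.
#'
#' @param feature_matrix Entities x features matrix; binary (0/1) for
#'   `metric = "jaccard"`, any categorical values for `"hamming"`.
#' @param metric `"jaccard"` or `"hamming"`.
#' @return Newick string with branch lengths.
#' @export
similarity_tree <- function(feature_matrix,
                            metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (nrow(feature_matrix) < 2)
    stop("need at least 2 entities for a tree")
  if (is.null(rownames(feature_matrix)))
    rownames(feature_matrix) <- paste0("entity", seq_len(nrow(feature_matrix)))
  d <- if (metric == "jaccard") {
    storage.mode(feature_matrix) <- "numeric"
    stats::dist(feature_matrix, method = "binary")
  } else {
    n <- nrow(feature_matrix)
    dm <- matrix(0, n, n, dimnames = list(rownames(feature_matrix),
                                          rownames(feature_matrix)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <-
        mean(feature_matrix[i, ] != feature_matrix[j, ])
    }
    stats::as.dist(dm)
  }
  hc <- stats::hclust(d, method = "average")
  ape::write.tree(ape::as.phylo(hc))
}
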