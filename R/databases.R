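# Reaction / biomass databases and diet constraint tables.
#
# Databases are flat TSVs in the style of reconstruction-pipeline exports:
# one row per reaction template, stoichiometry written as a human-readable
# equation string ("2 a[c] + b[c] -> c[c]", "<=>" when reversible). The
# biomass database additionally keys rows by species and records the
# biomass metabolite and its drain so pan-genus assembly can exclude both.

#' Parse a reaction equation string
#'
#' Accepts `"2 a[c] + b[c] -> c[c]"` style strings; `"<=>"` marks a
#' reversible arrow, an empty side is allowed (boundary reactions).
#'
#' @param s Equation string.
#' @return Named numeric vector of signed coefficients (reactants
#'   negative), with attribute `reversible`.
#' @export
parse_stoichiometry <- function(s) {
  arrow <- if (grepl("<=>", s, fixed = TRUE)) "<=>"
           else if (grepl("->", s, fixed = TRUE)) "->"
           else stop("parse error: no reaction arrow in '", s, "'")
  sides <- strsplit(s, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^(?:([0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s+)?(\\S+)$", t))[[1]]
      if (length(m) == 0L || m[3] == "")
        stop("parse error: cannot parse term '", t, "' in '", s, "'")
      coef <- if (m[2] == "") 1 else as.numeric(m[2])
      out[m[3]] <- sign * coef + if (m[3] %in% names(out)) out[m[3]] else 0
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  coefs <- lhs
  for (met in names(rhs)) {
    coefs[met] <- rhs[met] + if (met %in% names(coefs)) coefs[met] else 0
  }
  coefs <- coefs[coefs != 0]
  if (length(coefs) == 0L)
    stop("parse error: empty stoichiometry in '", s, "'")
  attr(coefs, "reversible") <- arrow == "<=>"
  coefs
}

format_stoichiometry <- function(coefs, reversible) {
  term <- function(v, names) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 1, names, sprintf("%.15g %s", v, names)),
          collapse = " + ")
  }
  lhs <- coefs[coefs < 0]; rhs <- coefs[coefs > 0]
  paste(term(abs(lhs), names(lhs)),
        if (reversible) "<=>" else "->",
        term(rhs, names(rhs)))
}

#' Load reaction and biomass databases
#'
#' @param reaction_table TSV with columns `id`, `name`, `stoichiometry`,
#'   `lower_bound`, `upper_bound`, `subsystem` (optionally `gene_rule`).
#' @param biomass_table TSV with columns `species_id`, `reaction_id`,
#'   `stoichiometry`, `biomass_metabolite` (optionally `drain_id`, the
#'   demand reaction draining the biomass metabolite in the species model).
#' @return List with `$reactions` (`reaction_database`: named list of
#'   reaction templates) and `$biomass` (`biomass_database`: named list per
#'   species). Lookup of an id absent from a database is an error.
#' @export
load_databases <- function(reaction_table, biomass_table) {
  rt <- utils::read.delim(reaction_table, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("id", "name", "stoichiometry", "lower_bound", "upper_bound")
  if (!all(need %in% names(rt)))
    stop("reaction table must have columns: ", paste(need, collapse = ", "))
  rxndb <- list()
  for (k in seq_len(nrow(rt))) {
    coefs <- tryCatch(parse_stoichiometry(rt$stoichiometry[k]),
                      error = function(e)
                        stop("reaction table row ", k, " (", rt$id[k], "): ",
                             conditionMessage(e)))
    tmpl <- list(id = rt$id[k], name = rt$name[k],
                 stoichiometry = coefs,
                 lower_bound = rt$lower_bound[k],
                 upper_bound = rt$upper_bound[k],
                 subsystem = if (is.null(rt$subsystem)) "" else rt$subsystem[k],
                 gene_rule = if (is.null(rt$gene_rule)) "" else rt$gene_rule[k])
    if (rt$id[k] %in% names(rxndb)) {
      old <- rxndb[[rt$id[k]]]$stoichiometry
      if (!identical(sort(names(old)), sort(names(coefs))) ||
          any(abs(old[names(coefs)] - coefs) > 1e-12))
        stop("conflict error: reaction '", rt$id[k],
             "' appears twice with different stoichiometry")
    }
    rxndb[[rt$id[k]]] <- tmpl
  }
  class(rxndb) <- "reaction_database"

  bt <- utils::read.delim(biomass_table, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("species_id", "reaction_id", "stoichiometry", "biomass_metabolite")
  if (!all(need %in% names(bt)))
    stop("biomass table must have columns: ", paste(need, collapse = ", "))
  biodb <- list()
  for (k in seq_len(nrow(bt))) {
    coefs <- tryCatch(parse_stoichiometry(bt$stoichiometry[k]),
                      error = function(e)
                        stop("biomass table row ", k, " (", bt$species_id[k],
                             "): ", conditionMessage(e)))
    biodb[[bt$species_id[k]]] <- list(
      species_id = bt$species_id[k],
      reaction_id = bt$reaction_id[k],
      stoichiometry = coefs,
      biomass_metabolite = bt$biomass_metabolite[k],
      drain_id = if (is.null(bt$drain_id)) NA_character_ else bt$drain_id[k])
  }
  class(biodb) <- "biomass_database"
  list(reactions = rxndb, biomass = biodb)
}

#' Look up database entries
#'
#' @param db A `reaction_database` or `biomass_database`.
#' @param id Reaction id (or species id for a biomass database).
#' @return The stored template; missing ids are an error (lookups are
#'   total over the modeled namespace).
#' @export
db_lookup <- function(db, id) {
  if (!id %in% names(db))
    stop("lookup error: '", id, "' not in database")
  db[[id]]
}

#' Create a diet specification
#'
#' A diet is a set of bounds on exchange reactions (VMH convention:
#' uptake is the negative lower bound).
#'
#' @param name Diet name.
#' @param bounds `data.frame` with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`.
#' @return A `diet_spec`.
#' @export
diet_spec <- function(name, bounds) {
  bounds <- as.data.frame(bounds, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "lower_bound", "upper_bound") %in%
                  names(bounds)))
  if (any(bounds$lower_bound > bounds$upper_bound))
    stop("diet '", name, "': lower_bound > upper_bound")
  structure(list(name = name, bounds = bounds), class = "diet_spec")
}

#' Read a diet table
#'
#' Two dialects: two columns (exchange id, uptake magnitude as a positive
#' number mapped to `lower_bound = -value`, secretion left open at 1000),
#' matching VMH diet downloads; or three columns giving both bounds.
#'
#' @param path TSV path with a header row.
#' @param name Diet name; defaults to the file stem.
#' @return A `diet_spec`.
#' @export
read_diet <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 2L) {
    bounds <- data.frame(reaction_id = tab[[1]],
                         lower_bound = -abs(as.numeric(tab[[2]])),
                         upper_bound = 1000,
                         stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 3L) {
    bounds <- data.frame(reaction_id = tab[[1]],
                         lower_bound = as.numeric(tab[[2]]),
                         upper_bound = as.numeric(tab[[3]]),
                         stringsAsFactors = FALSE)
  } else stop("diet table must have 2 or 3 columns")
  diet_spec(name, bounds)
}

#' Write a diet table
#'
#' @param diet A `diet_spec`.
#' @param path Output TSV path (three-column dialect).
#' @return `path`, invisibly.
#' @export
write_diet <- function(diet, path) {
  utils::write.table(diet$bounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply diet constraints to a model
#'
#' Sets the bounds of every exchange reaction named in the diet; with
#' `close_unlisted = TRUE` (the default, mgPipe-style) every exchange
#' absent from the diet has its uptake closed (`lower_bound = 0`, the
#' secretion bound untouched). Diet ids absent from the model are reported
#' as a warning, not an error. Idempotent for a fixed diet.
#'
#' @param model A `metabolic_model`.
#' @param diet A `diet_spec`.
#' @param close_unlisted Close uptake of unlisted exchanges?
#' @return The constrained model.
#' @export
apply_diet <- function(model, diet, close_unlisted = TRUE) {
  model <- as_metabolic_model(model)
  stopifnot(inherits(diet, "diet_spec"))
  ex <- exchange_reactions(model)
  listed <- diet$bounds$reaction_id
  missing <- setdiff(listed, ex)
  if (length(missing))
    warning("diet '", diet$name, "': exchange(s) not in model: ",
            paste(missing, collapse = ", "))
  hit <- listed %in% ex
  if (any(hit))
    model <- set_bounds(model, listed[hit],
                        lower = diet$bounds$lower_bound[hit],
                        upper = diet$bounds$upper_bound[hit])
  if (close_unlisted) {
    rest <- setdiff(ex, listed)
    if (length(rest)) model <- set_bounds(model, rest, lower = 0)
  }
  model
}
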