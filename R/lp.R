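# Linear-programming backend.
#
# Flux balance analysis solves  max c'v  s.t.  S v = 0, lb <= v <= ub.
# Problems are written in CPLEX LP format and handed to GLPK's `glpsol`
# binary; one process per LP (models here are small, the solve itself is
# milliseconds). The constraint and bounds sections are rendered once per
# model and reused across the many objectives of an FVA sweep.

glpsol_path <- function() {
  p <- Sys.which("glpsol")
  if (p == "") stop("glpsol (GLPK) not found on PATH")
  p
}

# Render the reusable part of the LP: 'Subject To' rows (S v = 0 per
# metabolite, skipping all-zero rows) and the 'Bounds' section.
lp_body <- function(S, lb, ub) {
  Tm <- methods::as(S, "TsparseMatrix")
  terms <- sprintf("%+.15g v%d", Tm@x, Tm@j + 1L)
  rows <- split(terms, Tm@i)
  cons <- vapply(seq_along(rows), function(k) {
    paste0(" r", names(rows)[k], ": ",
           paste(rows[[k]], collapse = " "), " = 0")
  }, character(1))
  n <- length(lb)
  fixed <- lb == ub
  bnd <- character(n)
  bnd[fixed] <- sprintf(" v%d = %.15g", which(fixed), lb[fixed])
  bnd[!fixed] <- sprintf(" %.15g <= v%d <= %.15g",
                         lb[!fixed], which(!fixed), ub[!fixed])
  list(cons = cons, bounds = bnd, n = n)
}

# Solve one LP given a prebuilt body, an objective (coefficients over
# variable indices) and optional extra constraint rows. Every variable
# appears in the objective (zero coefficients included) so that GLPK's
# column numbering — assigned by first appearance in the file — matches
# the model's reaction order, which lets us read the full-precision
# machine-readable solution back by index.
lp_solve_body <- function(body, obj_idx, obj_coef, maximize = TRUE,
                          extra_rows = character(0),
                          workdir = tempdir()) {
  coefs <- numeric(body$n)
  coefs[obj_idx] <- obj_coef
  obj_terms <- sprintf("%+.15g v%d", coefs, seq_len(body$n))
  txt <- c(if (maximize) "Maximize" else "Minimize",
           paste0(" obj: ", paste(obj_terms, collapse = " ")),
           "Subject To", body$cons, extra_rows,
           "Bounds", body$bounds, "End")
  fin <- file.path(workdir, "pg_problem.lp")
  fout <- file.path(workdir, "pg_solution.txt")
  writeLines(txt, fin)
  log <- suppressWarnings(
    system2(glpsol_path(), c("--lp", shQuote(fin), "-w", shQuote(fout)),
            stdout = TRUE, stderr = FALSE))
  rc <- attr(log, "status")
  if ((!is.null(rc) && rc != 0L) || !file.exists(fout))
    stop("glpsol failed (exit code ", rc, ")")
  sol <- readLines(fout)
  sline <- strsplit(sol[grep("^s ", sol)[1]], " ", fixed = TRUE)[[1]]
  pstat <- sline[5]; dstat <- sline[6]
  objval <- as.numeric(sline[7])
  status <- if (pstat == "f" && dstat == "f") "optimal"
            else if (pstat %in% c("i", "n") ||
                     any(grepl("NO PRIMAL FEASIBLE", log))) "infeasible"
            else if (dstat %in% c("i", "n") ||
                     any(grepl("NO DUAL FEASIBLE|UNBOUNDED", log)))
              "unbounded"
            else "undefined"
  fluxes <- rep(NA_real_, body$n)
  jl <- sol[startsWith(sol, "j ")]
  if (length(jl)) {
    parts <- strsplit(jl, " ", fixed = TRUE)
    idx <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    val <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
    fluxes[idx] <- val
  }
  list(status = status, objective_value = objval, fluxes = fluxes)
}

model_lp_body <- function(model) {
  lp_body(model$S, model$reactions$lower_bound, model$reactions$upper_bound)
}

#' Flux balance analysis
#'
#' Maximizes flux through the model's objective reaction subject to
#' steady-state mass balance (`S v = 0`) and the flux bounds.
#'
#' @param model A `metabolic_model` (or the `$model` of a pan-genus /
#'   community object).
#' @param maximize Maximize (default) or minimize the objective.
#' @return List with `status` (`"optimal"`, `"infeasible"`, ...),
#'   `objective_value`, and `fluxes` (named by reaction id; `NA` when the
#'   solver reports no solution).
#' @export
fba <- function(model, maximize = TRUE) {
  model <- as_metabolic_model(model)
  validate_model(model)
  body <- model_lp_body(model)
  j <- match(model$objective, model$reactions$id)
  res <- lp_solve_body(body, j, 1, maximize = maximize)
  names(res$fluxes) <- model$reactions$id
  if (res$status != "optimal") res$objective_value <- NA_real_
  res
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject
#' to the model constraints plus a near-optimality cut
#' `objective >= fraction_of_optimum * optimum`. The maximum flux of an
#' exchange reaction is its production (secretion) potential, the minimum
#' its uptake potential.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to scan; defaults to all exchanges.
#' @param fraction_of_optimum Fraction of the FBA optimum to enforce, in
#'   `[0, 1]`; `0` drops the cut entirely (bounds-only ranges). Default
#'   0.9999 avoids the degenerate alternate-optima face at exactly 1.
#' @return Object of class `fva_result`: data frame with columns
#'   `reaction_id`, `min_flux`, `max_flux`, plus attributes
#'   `fraction_of_optimum` and `optimum`.
#' @export
fva <- function(model, reaction_ids = exchange_reactions(model),
                fraction_of_optimum = 0.9999) {
  model <- as_metabolic_model(model)
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  validate_model(model)
  body <- model_lp_body(model)
  jobj <- match(model$objective, model$reactions$id)
  opt <- lp_solve_body(body, jobj, 1, maximize = TRUE)
  if (opt$status != "optimal")
    stop("FVA: model is ", opt$status, " under its constraints")
  extra <- character(0)
  if (fraction_of_optimum > 0)
    extra <- sprintf(" fopt: +1 v%d >= %.15g", jobj,
                     fraction_of_optimum * opt$objective_value)
  j <- match(reaction_ids, model$reactions$id)
  if (anyNA(j)) stop("unknown reaction id(s): ",
                     paste(reaction_ids[is.na(j)], collapse = ", "))
  lo <- hi <- numeric(length(j))
  for (k in seq_along(j)) {
    lo[k] <- lp_solve_body(body, j[k], 1, FALSE, extra)$objective_value
    hi[k] <- lp_solve_body(body, j[k], 1, TRUE, extra)$objective_value
  }
  res <- data.frame(reaction_id = reaction_ids, min_flux = lo,
                    max_flux = hi, stringsAsFactors = FALSE)
  attr(res, "fraction_of_optimum") <- fraction_of_optimum
  attr(res, "optimum") <- opt$objective_value
  class(res) <- c("fva_result", "data.frame")
  res
}

# Accept wrapper objects (pan-genus, community) wherever a plain model is
# expected.
as_metabolic_model <- function(x) {
  if (inherits(x, "metabolic_model")) return(x)
  if (!is.null(x$model) && inherits(x$model, "metabolic_model"))
    return(x$model)
  stop("not a metabolic model: ", paste(class(x), collapse = "/"))
}
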