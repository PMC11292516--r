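# SBML Level 3 + FBC version 2 reader/writer.
#
# On-disk ids follow the COBRA convention: metabolites prefixed "M_",
# reactions "R_", and characters outside [A-Za-z0-9_] encoded as
# "__<ascii>__" (so "EX_glc(e)" <-> "R_EX_glc__40__e__41__"), which keeps
# VMH-style bracket/parenthesis ids lossless and readable by COBRApy.
# Gene rules and subsystems travel in the reaction notes body
# (GENE_ASSOCIATION / SUBSYSTEM lines), the long-standing COBRA practice.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_encode_id <- function(x, prefix) {
  enc <- vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    chars <- vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch
      else sprintf("__%d__", utf8ToInt(ch))
    }, character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  paste0(prefix, enc)
}

sbml_decode_id <- function(x, prefix) {
  x <- sub(paste0("^", prefix), "", x)
  m <- gregexpr("__([0-9]+)__", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(toks) {
    vapply(toks, function(t) {
      intToUtf8(as.integer(gsub("__", "", t, fixed = TRUE)))
    }, character(1))
  })
  x
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a metabolic model to SBML
#'
#' Serializes a model as SBML Level 3 Version 1 with the FBC v2 extension:
#' flux bounds as shared parameters, the objective as an FBC maximize
#' objective, formulas/charges as FBC species attributes.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path (`.xml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  mets <- model$metabolites
  rxns <- model$reactions
  met_sid <- sbml_encode_id(mets$id, "M_")
  rxn_sid <- sbml_encode_id(rxns$id, "R_")

  comps <- unique(mets$compartment)
  comp_xml <- sprintf('      <compartment id="%s" constant="true"/>', comps)

  charge <- ifelse(is.na(mets$charge), 0, mets$charge)
  sp_xml <- sprintf(paste0(
    '      <species id="%s" name="%s" compartment="%s"',
    ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
    ' constant="false" fbc:charge="%d" fbc:chemicalFormula="%s"/>'),
    met_sid, xml_escape_attr(mets$name), mets$compartment,
    as.integer(charge), mets$formula)

  bvals <- sort(unique(c(rxns$lower_bound, rxns$upper_bound)))
  bid <- function(v) sprintf("pg_bnd_%d", match(v, bvals))
  par_xml <- sprintf(
    '      <parameter id="pg_bnd_%d" value="%.17g" constant="true"/>',
    seq_along(bvals), bvals)

  Tm <- methods::as(model$S, "TsparseMatrix")
  by_rxn <- split(data.frame(i = Tm@i + 1L, x = Tm@x), Tm@j + 1L)
  rx_xml <- vapply(seq_len(nrow(rxns)), function(j) {
    ent <- by_rxn[[as.character(j)]]
    reac <- ent[ent$x < 0, , drop = FALSE]
    prod <- ent[ent$x > 0, , drop = FALSE]
    sref <- function(d) sprintf(
      '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
      met_sid[d$i], abs(d$x))
    notes <- character(0)
    if (nzchar(rxns$gene_rule[j]) || nzchar(rxns$subsystem[j])) {
      notes <- c('        <notes>',
                 '          <body xmlns="http://www.w3.org/1999/xhtml">',
                 if (nzchar(rxns$gene_rule[j]))
                   sprintf("            <p>GENE_ASSOCIATION: %s</p>",
                           xml_escape_attr(rxns$gene_rule[j])),
                 if (nzchar(rxns$subsystem[j]))
                   sprintf("            <p>SUBSYSTEM: %s</p>",
                           xml_escape_attr(rxns$subsystem[j])),
                 '          </body>', '        </notes>')
    }
    paste(c(sprintf(paste0(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false"',
      ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      rxn_sid[j], xml_escape_attr(rxns$name[j]),
      if (rxns$lower_bound[j] < 0) "true" else "false",
      bid(rxns$lower_bound[j]), bid(rxns$upper_bound[j])),
      notes,
      if (nrow(reac)) c("        <listOfReactants>", sref(reac),
                        "        </listOfReactants>"),
      if (nrow(prod)) c("        <listOfProducts>", sref(prod),
                        "        </listOfProducts>"),
      "      </reaction>"), collapse = "\n")
  }, character(1))

  obj_sid <- rxn_sid[match(model$objective, rxns$id)]
  txt <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1"',
                   ' fbc:required="false">'), SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="false">',
            sbml_encode_id(model$id, "")),
    "    <listOfCompartments>", comp_xml, "    </listOfCompartments>",
    "    <listOfSpecies>", sp_xml, "    </listOfSpecies>",
    "    <listOfParameters>", par_xml, "    </listOfParameters>",
    "    <listOfReactions>", rx_xml, "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            obj_sid),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>", "</sbml>")
  xml2::read_xml(paste(txt, collapse = "\n"))  # well-formedness guard
  writeLines(txt, path)
  invisible(path)
}

xp <- function(node, path) {
  xml2::xml_find_all(node, path)
}

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 3 with the FBC extension (the format AGORA-style
#' reconstructions are distributed in). Flux-bound parameters, FBC charges
#' and formulas, the active objective, and COBRA-style notes
#' (GENE_ASSOCIATION, SUBSYSTEM) are recovered.
#'
#' @param path SBML file path.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: not well-formed XML: ",
                                           conditionMessage(e)))
  mnode <- xp(doc, ".//*[local-name()='model']")
  if (length(mnode) == 0) stop("format error: no <model> element")
  mnode <- mnode[[1]]
  model_id <- sbml_decode_id(xml2::xml_attr(mnode, "id"), "")
  if (is.na(model_id)) model_id <- "model"

  pnodes <- xp(mnode, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                           xml2::xml_attr(pnodes, "id"))

  snodes <- xp(mnode, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(snodes) == 0) stop("format error: model has no species")
  sattrs <- lapply(snodes, xml2::xml_attrs)
  # xml2 reports namespaced attributes by local name (or prefixed,
  # depending on the document); accept either spelling
  gattr <- function(attrs, key, default = NA_character_) {
    for (k in c(key, sub("^fbc:", "", key))) {
      if (k %in% names(attrs)) return(unname(attrs[k]))
    }
    default
  }
  sp_sid <- vapply(sattrs, gattr, character(1), key = "id")
  mets <- data.frame(
    id = sbml_decode_id(sp_sid, "M_"),
    name = vapply(sattrs, gattr, character(1), key = "name", default = ""),
    compartment = vapply(sattrs, gattr, character(1), key = "compartment"),
    formula = vapply(sattrs, gattr, character(1),
                     key = "fbc:chemicalFormula", default = ""),
    charge = as.integer(vapply(sattrs, gattr, character(1),
                               key = "fbc:charge", default = "0")),
    stringsAsFactors = FALSE)

  rnodes <- xp(mnode, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rnodes) == 0) stop("format error: model has no reactions")
  rids_sid <- xml2::xml_attr(rnodes, "id")
  if (anyDuplicated(rids_sid))
    stop("integrity error: duplicate reaction ids in SBML: ",
         paste(unique(rids_sid[duplicated(rids_sid)]), collapse = ", "))
  n_r <- length(rnodes)
  lb <- ub <- numeric(n_r)
  gene <- subsys <- character(n_r)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (j in seq_len(n_r)) {
    rn <- rnodes[[j]]
    attrs <- xml2::xml_attrs(rn)
    lbp <- gattr(attrs, "fbc:lowerFluxBound")
    ubp <- gattr(attrs, "fbc:upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(pvals)) lb[j] <- pvals[[lbp]]
    else lb[j] <- if (identical(gattr(attrs, "reversible"), "true")) -1000 else 0
    if (!is.na(ubp) && ubp %in% names(pvals)) ub[j] <- pvals[[ubp]]
    else ub[j] <- 1000
    ps <- xml2::xml_text(xp(rn, ".//*[local-name()='p']"))
    g <- grep("^\\s*GENE_ASSOCIATION:", ps, value = TRUE)
    s <- grep("^\\s*SUBSYSTEM:", ps, value = TRUE)
    gene[j] <- if (length(g)) trimws(sub("^\\s*GENE_ASSOCIATION:", "", g[1])) else ""
    subsys[j] <- if (length(s)) trimws(sub("^\\s*SUBSYSTEM:", "", s[1])) else ""
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      srefs <- xp(rn, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (length(srefs) == 0) next
      sp <- xml2::xml_attr(srefs, "species")
      st <- as.numeric(xml2::xml_attr(srefs, "stoichiometry"))
      st[is.na(st)] <- 1
      i <- match(sp, sp_sid)
      if (anyNA(i))
        stop("integrity error: reaction '", rids_sid[j],
             "' references undeclared species: ",
             paste(sp[is.na(i)], collapse = ", "))
      trip_i[[length(trip_i) + 1L]] <- i
      trip_j[[length(trip_j) + 1L]] <- rep(j, length(i))
      trip_x[[length(trip_x) + 1L]] <- side * st
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(nrow(mets), n_r))
  rxns <- data.frame(
    id = sbml_decode_id(rids_sid, "R_"),
    name = vapply(rnodes, function(n) {
      v <- xml2::xml_attr(n, "name"); if (is.na(v)) "" else v
    }, character(1)),
    lower_bound = lb, upper_bound = ub,
    gene_rule = gene, subsystem = subsys,
    stringsAsFactors = FALSE)

  fobj <- xp(mnode, ".//*[local-name()='fluxObjective']")
  if (length(fobj)) {
    osid <- xml2::xml_attr(fobj[[1]], "reaction")
    objective <- rxns$id[match(osid, rids_sid)]
    if (is.na(objective))
      stop("integrity error: objective reaction '", osid, "' not in model")
  } else {
    objective <- rxns$id[n_r]
  }
  metabolic_model(model_id, mets, rxns, S, objective)
}
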