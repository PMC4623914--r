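# SBML Level 2 reader/writer in the COBRA dialect: flux bounds and objective
# coefficients live in kineticLaw LOCAL parameters (LOWER_BOUND, UPPER_BOUND,
# OBJECTIVE_COEFFICIENT), gene associations and subsystems in reaction notes,
# elemental formulas in species notes ("FORMULA: ...") or as a trailing
# "_C6H12O6" suffix on the species name.

.note_field <- function(node, keys) {
  ps <- xml2::xml_find_all(
    node, ".//*[local-name()='notes']//*[local-name()='p']")
  for (p in ps) {
    txt <- trimws(xml2::xml_text(p))
    for (key in keys) {
      pat <- paste0("^", key, "\\s*:\\s*")
      if (grepl(pat, txt, ignore.case = TRUE))
        return(trimws(sub(pat, "", txt, ignore.case = TRUE)))
    }
  }
  NA_character_
}

.formula_from_name <- function(name) {
  m <- regmatches(name, regexpr("_([A-Za-z0-9]+)$", name))
  if (!length(m)) return(NA_character_)
  cand <- sub("^_", "", m)
  if (grepl("^([A-Z][a-z]?[0-9]*\\.?[0-9]*)+$", cand)) cand else NA_character_
}

.detect_external <- function(compartments) {
  # the compartment that contains the others, or a conventional id
  cand <- setdiff(compartments$outside, NA)
  cand <- setdiff(unique(cand), character())
  inside_of_nothing <- compartments$id[is.na(compartments$outside) |
                                         !nzchar(compartments$outside)]
  conventional <- intersect(tolower(compartments$id),
                            c("e", "ext", "external", "extracellular", "c_e"))
  if (length(cand)) {
    top <- intersect(cand, inside_of_nothing)
    if (length(top)) return(top[1])
  }
  if (length(conventional))
    return(compartments$id[match(conventional[1], tolower(compartments$id))])
  if (length(inside_of_nothing)) return(inside_of_nothing[1])
  compartments$id[1]
}

#' Read an SBML Level 2 metabolic model
#'
#' Accepts the COBRA kinetic-law dialect (local `LOWER_BOUND` /
#' `UPPER_BOUND` / `OBJECTIVE_COEFFICIENT` parameters) as used by
#' toolbox-era genome-scale reconstructions. Reactions without explicit
#' bounds receive (-1000, 1000) when declared reversible and (0, 1000)
#' otherwise; a message reports how many were defaulted. Boundary-condition
#' species are kept in the metabolite table but excluded from the
#' steady-state constraint.
#'
#' @param path path to an SBML file.
#' @param external optional id of the external compartment; auto-detected
#'   from the compartment hierarchy when `NULL`.
#' @return a [metabolic_model].
#' @export
read_sbml <- function(path, external = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ",
                                           basename(path), ": ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", basename(path))
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  cnodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  if (!length(cnodes)) stop("SBML parse failure: no compartments")
  compartments <- data.frame(
    id = xml2::xml_attr(cnodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(cnodes, "name")),
                  xml2::xml_attr(cnodes, "id"), xml2::xml_attr(cnodes, "name")),
    outside = xml2::xml_attr(cnodes, "outside"),
    stringsAsFactors = FALSE)
  if (is.null(external)) external <- .detect_external(compartments)

  snodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(snodes)) stop("SBML parse failure: no species")
  sid <- xml2::xml_attr(snodes, "id")
  sname <- xml2::xml_attr(snodes, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  formula <- vapply(seq_along(snodes), function(i) {
    f <- .note_field(snodes[[i]], c("FORMULA", "CHEMICAL FORMULA"))
    if (is.na(f)) f <- .formula_from_name(sname[i])
    f
  }, character(1))
  charge <- suppressWarnings(as.integer(xml2::xml_attr(snodes, "charge")))
  metabolites <- data.frame(
    id = sid, name = sname,
    compartment = xml2::xml_attr(snodes, "compartment"),
    formula = formula, charge = charge,
    boundary = xml2::xml_attr(snodes, "boundaryCondition") %in%
      c("true", "1"),
    stringsAsFactors = FALSE)
  if (anyNA(metabolites$compartment))
    stop("SBML parse failure: species without compartment: ",
         sid[is.na(metabolites$compartment)][1])

  rnodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rnodes)) stop("SBML parse failure: no reactions")
  nr <- length(rnodes)
  rid <- xml2::xml_attr(rnodes, "id")
  rname <- xml2::xml_attr(rnodes, "name")
  rname[is.na(rname)] <- rid[is.na(rname)]
  reversible <- !(xml2::xml_attr(rnodes, "reversible") %in% c("false", "0"))

  met_index <- setNames(seq_len(nrow(metabolites)), metabolites$id)
  tri_i <- integer(); tri_j <- integer(); tri_x <- numeric()
  lb <- numeric(nr); ub <- numeric(nr); objective <- numeric(nr)
  gene_rule <- character(nr); subsystem <- character(nr)
  n_default <- 0L
  for (j in seq_len(nr)) {
    node <- rnodes[[j]]
    gene_rule[j] <- {
      g <- .note_field(node, c("GENE_ASSOCIATION", "GENE ASSOCIATION",
                               "GPR_ASSOCIATION"))
      if (is.na(g)) "" else g
    }
    subsystem[j] <- {
      s <- .note_field(node, c("SUBSYSTEM"))
      if (is.na(s)) "" else s
    }
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        k <- met_index[sp]
        if (is.na(k))
          stop("SBML parse failure: reaction ", rid[j],
               " references unknown species ", sp)
        tri_i <<- c(tri_i, k); tri_j <<- c(tri_j, j)
        tri_x <<- c(tri_x, sign * st)
      }
    }
    add_side(".//listOfReactants/speciesReference", -1)
    add_side(".//listOfProducts/speciesReference", +1)
    pars <- xml2::xml_find_all(
      node, ".//kineticLaw/listOfParameters/parameter")
    pid <- xml2::xml_attr(pars, "id")
    pval <- as.numeric(xml2::xml_attr(pars, "value"))
    getp <- function(key) if (key %in% pid) pval[match(key, pid)] else NA_real_
    lb[j] <- getp("LOWER_BOUND"); ub[j] <- getp("UPPER_BOUND")
    objective[j] <- {
      o <- getp("OBJECTIVE_COEFFICIENT"); if (is.na(o)) 0 else o
    }
    if (is.na(lb[j]) || is.na(ub[j])) {
      n_default <- n_default + 1L
      if (is.na(lb[j])) lb[j] <- if (reversible[j]) -1000 else 0
      if (is.na(ub[j])) ub[j] <- 1000
    }
  }
  if (n_default > 0)
    message("read_sbml: defaulted bounds for ", n_default,
            " reaction(s) without explicit LOWER_BOUND/UPPER_BOUND")

  pseudo_note <- vapply(seq_len(nr), function(j) {
    p <- .note_field(rnodes[[j]], "PSEUDOREACTION")
    !is.na(p) && tolower(p) %in% c("true", "1", "yes")
  }, logical(1))
  pseudo <- pseudo_note |
    grepl("biomass|^ATPM$|maintenance|^DM_|^SINK_|^demand",
          rid, ignore.case = TRUE) |
    grepl("biomass|maintenance", rname, ignore.case = TRUE)
  reactions <- data.frame(
    id = rid, name = rname, lb = lb, ub = ub,
    gene_rule = gene_rule, subsystem = subsystem,
    objective = objective, pseudo = pseudo, stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                            dims = c(nrow(metabolites), nr))
  metabolic_model(model_id, metabolites, reactions, S, compartments, external)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a model as COBRA-dialect SBML Level 2
#'
#' Emits the kinetic-law parameter encoding of bounds and objective
#' coefficients so that `read_sbml(write_sbml(m))` round-trips
#' stoichiometry, bounds, objective and gene rules exactly.
#'
#' @param model a [metabolic_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2" xmlns:html="http://www.w3.org/1999/xhtml" level="2" version="1">')
  w(sprintf('<model id="%s" name="%s">', esc(model$id), esc(model$id)))
  w('<listOfCompartments>')
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    out <- if (!is.na(cp$outside) && nzchar(cp$outside))
      sprintf(' outside="%s"', esc(cp$outside)) else ""
    w(sprintf('<compartment id="%s" name="%s"%s/>', esc(cp$id), esc(cp$name), out))
  }
  w('</listOfCompartments>')
  w('<listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    chg <- if (!is.na(mt$charge)) sprintf(' charge="%d"', mt$charge) else ""
    bnd <- if (isTRUE(mt$boundary)) ' boundaryCondition="true"' else ""
    if (!is.na(mt$formula) && nzchar(mt$formula)) {
      w(sprintf('<species id="%s" name="%s" compartment="%s"%s%s>',
                esc(mt$id), esc(mt$name), esc(mt$compartment), chg, bnd))
      w('<notes><html:body><html:p>FORMULA: ', esc(mt$formula),
        '</html:p></html:body></notes>')
      w('</species>')
    } else {
      w(sprintf('<species id="%s" name="%s" compartment="%s"%s%s/>',
                esc(mt$id), esc(mt$name), esc(mt$compartment), chg, bnd))
    }
  }
  w('</listOfSpecies>')
  w('<listOfReactions>')
  for (j in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[j, ]
    rev <- if (rx$lb < 0) "true" else "false"
    w(sprintf('<reaction id="%s" name="%s" reversible="%s">',
              esc(rx$id), esc(rx$name), rev))
    notes <- character()
    if (nzchar(rx$gene_rule))
      notes <- c(notes, paste0('<html:p>GENE_ASSOCIATION: ',
                               esc(rx$gene_rule), '</html:p>'))
    if (nzchar(rx$subsystem))
      notes <- c(notes, paste0('<html:p>SUBSYSTEM: ',
                               esc(rx$subsystem), '</html:p>'))
    if (isTRUE(rx$pseudo))
      notes <- c(notes, '<html:p>PSEUDOREACTION: true</html:p>')
    if (length(notes))
      w('<notes><html:body>', paste(notes, collapse = ""),
        '</html:body></notes>')
    coef <- model$S[, j]
    idx <- which(coef != 0)
    lhs <- idx[coef[idx] < 0]; rhs <- idx[coef[idx] > 0]
    side <- function(tag, ids, sgn) {
      if (!length(ids)) return()
      w(sprintf('<listOf%s>', tag))
      for (k in ids)
        w(sprintf('<speciesReference species="%s" stoichiometry="%s"/>',
                  esc(model$metabolites$id[k]), .fmt_num(sgn * coef[k])))
      w(sprintf('</listOf%s>', tag))
    }
    side("Reactants", lhs, -1)
    side("Products", rhs, +1)
    w('<kineticLaw>')
    w('<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>')
    w('<listOfParameters>')
    w(sprintf('<parameter id="LOWER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              .fmt_num(rx$lb)))
    w(sprintf('<parameter id="UPPER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              .fmt_num(rx$ub)))
    w(sprintf('<parameter id="OBJECTIVE_COEFFICIENT" value="%s"/>',
              .fmt_num(rx$objective)))
    w('</listOfParameters>')
    w('</kineticLaw>')
    w('</reaction>')
  }
  w('</listOfReactions>')
  w('</model>')
  w('</sbml>')
  invisible(path)
}

#' Dump a model as JSON (debugging aid)
#'
#' @param model a [metabolic_model].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  S <- Matrix::summary(model$S)
  obj <- list(
    id = model$id,
    metabolites = model$metabolites,
    reactions = model$reactions,
    stoichiometry = data.frame(
      metabolite = model$metabolites$id[S$i],
      reaction = model$reactions$id[S$j],
      coefficient = S$x),
    compartments = model$compartments,
    external = model$external,
    couplings = model$couplings)
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
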