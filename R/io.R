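# Network serialization.
#
# Two formats round-trip losslessly:
#  * SBML Level 3 Version 1 with the FBC v2 package (bounds as parameters,
#    GPRs as fbc:geneProductAssociation trees, objective coefficients as
#    fbc:fluxObjectives). Ids are prefixed M_/R_/G_ on write and the prefixes
#    stripped on read, following the common convention.
#  * A documented JSON dialect (format "omvflux-network", version 1) that
#    mirrors the same content and is easy to write by hand for toy fixtures:
#    {format, version, compartments, biomass_reaction, genes,
#     metabolites: [{id, name, compartment, formula, charge}],
#     reactions: [{id, name, stoichiometry: {met: coef}, lower_bound,
#                  upper_bound, gpr, objective_coefficient}]}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic network model
#'
#' @param path file path
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension)
#' @return a [metabolic_network()]
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format, sbml = read_model_sbml(path), json = read_model_json(path))
}

#' Write a metabolic network model
#'
#' @param net a [metabolic_network()]
#' @param path output path
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension)
#' @return `path`, invisibly
#' @export
write_model <- function(net, path, format = c("auto", "sbml", "json")) {
  stopifnot(inherits(net, "metabolic_network"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, sbml = write_model_sbml(net, path), json = write_model_json(net, path))
  invisible(path)
}

## ---- JSON dialect ----------------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in '", path, "': ",
                                           conditionMessage(e)))
  if (!identical(doc$format, "omvflux-network")) {
    stop("not an omvflux-network JSON file (missing format tag): ", path)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment,
    formula = m$formula %||% NA_character_,
    charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
    stringsAsFactors = FALSE)))
  rxns <- lapply(doc$reactions, function(r) list(
    id = r$id, name = r$name %||% r$id,
    stoichiometry = unlist(r$stoichiometry),
    lower_bound = r$lower_bound, upper_bound = r$upper_bound,
    gpr = r$gpr %||% "",
    objective_coefficient = r$objective_coefficient %||% 0))
  metabolic_network(
    metabolites = mets, reactions = rxns,
    biomass_reaction_id = doc$biomass_reaction %||% NA_character_,
    genes = if (!is.null(doc$genes)) unlist(doc$genes),
    compartments = if (!is.null(doc$compartments)) names(doc$compartments)
  )
}

write_model_json <- function(net, path) {
  comp_names <- net$compartments
  compartments <- stats::setNames(as.list(comp_names), comp_names)
  doc <- list(
    format = "omvflux-network",
    version = 1L,
    compartments = compartments,
    biomass_reaction = net$biomass_reaction_id,
    genes = as.list(net$genes),
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
      m <- net$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(net$reactions)), function(j) {
      r <- net$reactions[j, ]
      st <- net$stoichiometry[, j]
      st <- st[st != 0]
      list(id = r$id, name = r$name,
           stoichiometry = as.list(st),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gpr = r$gpr, objective_coefficient = r$objective_coefficient)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

## ---- SBML L3 + FBC v2 ------------------------------------------------------

sbml_sid <- function(prefix, id) {
  sid <- gsub("[^A-Za-z0-9_]", "__", id)
  paste0(prefix, sid)
}
strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

write_model_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  L <- character(0)
  push <- function(...) L[length(L) + 1L] <<- paste0(...)

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
       '" level="3" version="1" fbc:required="false">')
  push('  <model id="model" fbc:strict="true">')

  push('    <listOfCompartments>')
  for (cc in net$compartments) {
    push('      <compartment id="', esc(cc), '" constant="true"/>')
  }
  push('    </listOfCompartments>')

  push('    <listOfSpecies>')
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    extra <- ""
    if (!is.na(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    if (!is.na(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    push('      <species id="', sbml_sid("M_", m$id), '" name="', esc(m$name),
         '" compartment="', esc(m$compartment),
         '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
         extra, '/>')
  }
  push('    </listOfSpecies>')

  # flux bounds as shared parameters
  bounds <- sort(unique(c(net$reactions$lower_bound, net$reactions$upper_bound)))
  par_id <- function(v) paste0("bnd_", match(v, bounds))
  push('    <listOfParameters>')
  for (v in bounds) {
    push('      <parameter id="', par_id(v), '" value="', num(v),
         '" constant="true" sboTerm="SBO:0000626"/>')
  }
  push('    </listOfParameters>')

  gpa_xml <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (is.character(ast)) {
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="',
                    sbml_sid("G_", ast), '"/>'))
    }
    tag <- paste0("fbc:", ast$op)
    inner <- vapply(ast$args, gpa_xml, character(1), indent = indent + 2L)
    paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"), "\n", pad, "</", tag, ">")
  }

  push('    <listOfReactions>')
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    st <- net$stoichiometry[, j]
    st <- st[st != 0]
    push('      <reaction id="', sbml_sid("R_", r$id), '" name="', esc(r$name),
         '" reversible="', tolower(r$lower_bound < 0), '" fast="false"',
         ' fbc:lowerFluxBound="', par_id(r$lower_bound),
         '" fbc:upperFluxBound="', par_id(r$upper_bound), '">')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      push('        <listOfReactants>')
      for (k in seq_along(reac)) {
        push('          <speciesReference species="', sbml_sid("M_", names(reac)[k]),
             '" stoichiometry="', num(-reac[k]), '" constant="true"/>')
      }
      push('        </listOfReactants>')
    }
    if (length(prod)) {
      push('        <listOfProducts>')
      for (k in seq_along(prod)) {
        push('          <speciesReference species="', sbml_sid("M_", names(prod)[k]),
             '" stoichiometry="', num(prod[k]), '" constant="true"/>')
      }
      push('        </listOfProducts>')
    }
    ast <- parse_gpr(r$gpr)
    if (!is.null(ast)) {
      push('        <fbc:geneProductAssociation>')
      push(gpa_xml(ast, 10L))
      push('        </fbc:geneProductAssociation>')
    }
    push('      </reaction>')
  }
  push('    </listOfReactions>')

  obj <- net$reactions[net$reactions$objective_coefficient != 0, ]
  push('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  push('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  if (nrow(obj)) {
    push('        <fbc:listOfFluxObjectives>')
    for (j in seq_len(nrow(obj))) {
      push('          <fbc:fluxObjective fbc:reaction="', sbml_sid("R_", obj$id[j]),
           '" fbc:coefficient="', num(obj$objective_coefficient[j]), '"/>')
    }
    push('        </fbc:listOfFluxObjectives>')
  }
  push('      </fbc:objective>')
  push('    </fbc:listOfObjectives>')

  if (length(net$genes)) {
    push('    <fbc:listOfGeneProducts>')
    for (g in net$genes) {
      push('      <fbc:geneProduct fbc:id="', sbml_sid("G_", g),
           '" fbc:label="', esc(g), '"/>')
    }
    push('    </fbc:listOfGeneProducts>')
  }
  push('  </model>')
  push('</sbml>')
  writeLines(L, path, useBytes = TRUE)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(model))) stop("SBML file has no <model> element: ", path)

  att <- function(node, name) xml2::xml_attr(node, name)

  comp_nodes <- xml2::xml_find_all(model, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- vapply(comp_nodes, att, character(1), name = "id")

  par_nodes <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(
    as.numeric(vapply(par_nodes, att, character(1), name = "value")),
    vapply(par_nodes, att, character(1), name = "id"))

  sp_nodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(vapply(sp_nodes, att, character(1), name = "id"), "M_"),
    name = vapply(sp_nodes, function(n) att(n, "name") %|NA|% "", character(1)),
    compartment = vapply(sp_nodes, att, character(1), name = "compartment"),
    formula = vapply(sp_nodes, att, character(1), name = "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp_nodes, att, character(1), name = "charge"))),
    stringsAsFactors = FALSE)
  mets$name[!nzchar(mets$name)] <- mets$id[!nzchar(mets$name)]

  gene_nodes <- xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_ids <- strip_prefix(vapply(gene_nodes, att, character(1), name = "id"), "G_")
  gene_labels <- vapply(gene_nodes, att, character(1), name = "label")
  gene_map <- stats::setNames(ifelse(is.na(gene_labels), gene_ids, gene_labels),
                              vapply(gene_nodes, att, character(1), name = "id"))

  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- att(node, "geneProduct")
      g <- gene_map[ref]
      return(unname(if (is.na(g)) strip_prefix(ref, "G_") else g))
    }
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, parse_gpa))
  }

  # objective coefficients
  fo_nodes <- xml2::xml_find_all(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj_map <- stats::setNames(
    as.numeric(vapply(fo_nodes, att, character(1), name = "coefficient")),
    strip_prefix(vapply(fo_nodes, att, character(1), name = "reaction"), "R_"))

  rxn_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rxn_nodes, function(node) {
    rid <- strip_prefix(att(node, "id"), "R_")
    refs <- function(xp, sign) {
      nn <- xml2::xml_find_all(node, xp, ns)
      if (!length(nn)) return(numeric(0))
      stats::setNames(
        sign * as.numeric(vapply(nn, att, character(1), name = "stoichiometry")),
        strip_prefix(vapply(nn, att, character(1), name = "species"), "M_"))
    }
    st_r <- refs("./s:listOfReactants/s:speciesReference", -1)
    st_p <- refs("./s:listOfProducts/s:speciesReference", +1)
    st <- c(st_r, st_p)
    dangling <- setdiff(names(st), mets$id)
    if (length(dangling)) {
      stop("reaction '", rid, "' references undeclared metabolite(s): ",
           paste(dangling, collapse = ", "))
    }
    lb_ref <- att(node, "lowerFluxBound"); ub_ref <- att(node, "upperFluxBound")
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!is.na(xml2::xml_name(gpa))) {
      gpr <- deparse_gpr(parse_gpa(xml2::xml_child(gpa)))
    }
    nm <- att(node, "name")
    list(id = rid, name = if (is.na(nm) || !nzchar(nm)) rid else nm,
         stoichiometry = st,
         lower_bound = par_vals[[lb_ref]], upper_bound = par_vals[[ub_ref]],
         gpr = gpr,
         objective_coefficient = if (rid %in% names(obj_map)) obj_map[[rid]] else 0)
  })

  obj_rxns <- names(obj_map)[obj_map != 0]
  biomass <- if (length(obj_rxns)) obj_rxns[[1]] else NA_character_
  metabolic_network(
    metabolites = mets, reactions = rxns, biomass_reaction_id = biomass,
    genes = if (length(gene_map)) sort(unique(unname(gene_map))),
    compartments = compartments)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
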