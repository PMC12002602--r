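# SBML Level 3 Version 1 with the FBC v2 package, the community exchange
# format for constraint-based models. Identifiers are prefixed M_/R_/G_ on
# export (SBML SId rules) and stripped on import; gene ids containing
# characters outside [A-Za-z0-9_] are carried in fbc:label.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sid <- function(x) {
  if (grepl("[^A-Za-z0-9_]", x)) gsub("[^A-Za-z0-9_]", "_", x) else x
}

write_model_sbml <- function(model, path) {
  model <- sort_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15)
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', esc(sbml_sid(model$id)), '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (k in names(model$compartments)) {
    add('      <compartment id="', esc(k), '" name="',
        esc(model$compartments[[k]]), '" constant="true"/>')
  }
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (m in model$metabolites) {
    add('      <species id="M_', esc(m$id), '" name="', esc(m$name),
        '" compartment="', esc(m$compartment),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  add('    </listOfSpecies>')
  bounds <- sort(unique(c(
    vapply(model$reactions, `[[`, 0, "lower_bound"),
    vapply(model$reactions, `[[`, 0, "upper_bound"))))
  bnd_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", num(v)))
  add('    <listOfParameters>')
  for (v in bounds) {
    add('      <parameter id="', bnd_id(v), '" value="', num(v),
        '" constant="true"/>')
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    add('      <reaction id="R_', esc(r$id), '" name="', esc(r$name),
        '" reversible="', rev, '" fast="false" fbc:lowerFluxBound="',
        bnd_id(r$lower_bound), '" fbc:upperFluxBound="', bnd_id(r$upper_bound),
        '">')
    s <- r$stoichiometry
    for (side in c("react", "prod")) {
      sel <- if (side == "react") s[s < 0] else s[s > 0]
      if (length(sel) == 0L) next
      tag <- if (side == "react") "listOfReactants" else "listOfProducts"
      add('        <', tag, '>')
      for (mid in names(sel)) {
        add('          <speciesReference species="M_', esc(mid),
            '" stoichiometry="', num(abs(sel[[mid]])), '" constant="true"/>')
      }
      add('        </', tag, '>')
    }
    if (nzchar(r$gpr)) {
      add('        <fbc:geneProductAssociation>')
      add(gpr_to_fbc(parse_gpr(r$gpr)$tree, indent = 10L))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  add('          <fbc:fluxObjective fbc:reaction="R_', esc(model$objective),
      '" fbc:coefficient="1"/>')
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  if (length(model$genes) > 0L) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      add('      <fbc:geneProduct fbc:id="G_', esc(sbml_sid(g$id)),
          '" fbc:label="', esc(g$id), '"/>')
    }
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(L, path)
  invisible(path)
}

gpr_to_fbc <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (is.character(node)) {
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                  sbml_sid(node), '"/>'))
  }
  tag <- if (node$op == "and") "fbc:and" else "fbc:or"
  c(paste0(pad, "<", tag, ">"),
    unlist(lapply(node$args, gpr_to_fbc, indent = indent + 2L)),
    paste0(pad, "</", tag, ">"))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("'", path, "': no <model> element")
  att <- function(node, a) xml2::xml_attr(node, a)

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))
  if (length(compartments) == 0L) compartments <- default_compartments()

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(sp_nodes, function(nd) {
    id <- sub("^M_", "", att(nd, "id"))
    metabolite(id, name = att(nd, "name") %|na|% id,
               compartment = att(nd, "compartment"))
  })
  comp_of <- setNames(vapply(mets, `[[`, "", "compartment"),
                      vapply(mets, `[[`, "", "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           sub("^G_", "", xml2::xml_attr(gp_nodes, "id")),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(nd) {
    rid <- sub("^R_", "", att(nd, "id"))
    refs <- function(tag, sign) {
      sr <- xml2::xml_find_all(nd, paste0("./s:", tag, "/s:speciesReference"), ns)
      if (length(sr) == 0L) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")),
               sub("^M_", "", xml2::xml_attr(sr, "species")))
    }
    s <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (length(s) == 0L) stop("reaction '", rid, "' in '", path,
                              "': empty stoichiometry")
    lb_ref <- att(nd, "lowerFluxBound"); ub_ref <- att(nd, "upperFluxBound")
    reversible <- identical(att(nd, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else 1000
    gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      fbc_to_gpr(xml2::xml_child(gpa), gp_label)
    }
    # SBML has no reaction-kind slot: boundary kinds come from the id
    # prefix, transport from spanning more than one compartment
    kind <- if (startsWith(rid, "EX_")) "exchange"
            else if (startsWith(rid, "DM_")) "demand"
            else if (grepl("biomass", rid, ignore.case = TRUE)) "biomass"
            else if (length(unique(comp_of[names(s)])) > 1L) "transport"
            else "internal"
    reaction(rid, s, lower_bound = lb, upper_bound = ub,
             name = att(nd, "name") %|na|% rid, gpr = gpr, kind = kind)
  })

  obj_ref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop("'", path, "': no FBC objective found")
  }
  objective <- sub("^R_", "", xml2::xml_attr(obj_ref, "reaction"))

  genes <- lapply(unname(gp_label), gene)
  metabolic_model(reactions = rxns, metabolites = mets, genes = genes,
                  compartments = compartments, objective = objective,
                  id = att(mdl, "id") %|na|% "model")
}

fbc_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(if (ref %in% names(gp_label)) gp_label[[ref]] else sub("^G_", "", ref))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_to_gpr, "", gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
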