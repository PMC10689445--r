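SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

num_attr <- function(x) sprintf("%.17g", x)

#' Write a metabolic model as SBML Level 3 with flux bounds and objective
#'
#' Serializes the constraint-based subset: compartments, species,
#' reactions with bound parameters (`fbc` attributes), and a single
#' maximization objective on the biomass reaction.  Species and reaction
#' ids carry the conventional `M_`/`R_` prefixes.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))

  comps <- unique(model$metabolites$compartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
           "    </listOfCompartments>",
           "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    out <- c(out, sprintf(
      '      <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(m$compartment)))
  }
  out <- c(out, "    </listOfSpecies>")

  bnd <- reaction_bounds(model)
  vals <- sort(unique(c(bnd$lb, bnd$ub)))
  pid <- setNames(sprintf("bnd_%d", seq_along(vals)), num_attr(vals))
  out <- c(out, "    <listOfParameters>",
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   pid, names(pid)),
           "    </listOfParameters>",
           "    <listOfReactions>")
  for (rid in names(model$reactions)) {
    rx <- model$reactions[[rid]]
    rev <- rx$lower_bound < 0
    out <- c(out, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(rid), tolower(as.character(rev)),
      pid[[num_attr(rx$lower_bound)]], pid[[num_attr(rx$upper_bound)]]))
    s <- rx$stoichiometry
    react <- s[s < 0]; prod <- s[s > 0]
    if (length(react)) {
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                       esc(names(react)), num_attr(-as.numeric(react))),
               "        </listOfReactants>")
    }
    if (length(prod)) {
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                       esc(names(prod)), num_attr(as.numeric(prod))),
               "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out,
           "    </listOfReactions>",
           '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           "        <fbc:listOfFluxObjectives>",
           sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
                   esc(model$biomass_reaction_id)),
           "        </fbc:listOfFluxObjectives>",
           "      </fbc:objective>",
           "    </fbc:listOfObjectives>",
           "  </model>",
           "</sbml>")
  writeLines(out, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}

# xml2::xml_ns_strip leaves prefixed (fbc:) elements namespaced; match by
# local name and accept attributes with or without the fbc prefix.
xml_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

xml_attr_any <- function(node, name) {
  val <- xml2::xml_attr(node, name)
  if (is.na(val)) val <- xml2::xml_attr(node, paste0("fbc:", name))
  val
}

#' Read a metabolic model from SBML Level 3 (flux-bounds/objective subset)
#'
#' Supports the constraint-based subset written by [write_model_sbml()] and
#' by common reconstruction tools: species with compartments, reactions
#' with stoichiometries and flux-bound parameters, and a single `fbc`
#' objective identifying the biomass reaction.  Reactions without bound
#' annotations get the conventional defaults (-1000, 1000) when declared
#' reversible and (0, 1000) otherwise.  Documents using rules, events,
#' constraints or function definitions are rejected by construct name;
#' documents with zero or multiple active flux objectives are rejected.
#'
#' @param path SBML file path.
#' @return a validated `metabolic_model`.
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML document has no model element")

  for (construct in c("listOfRules", "listOfEvents", "listOfConstraints",
                      "listOfFunctionDefinitions")) {
    if (!inherits(xml2::xml_find_first(mdl, paste0("./", construct)),
                  "xml_missing"))
      stop("unsupported SBML construct: ", construct)
  }

  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML model has no species")
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("SBML model has no reactions")
  rxns <- list()
  for (node in rx_nodes) {
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    sto <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      met <- strip_prefix(xml2::xml_attr(ref, "species"), "M_")
      sto[met] <- -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      met <- strip_prefix(xml2::xml_attr(ref, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      sto[met] <- if (met %in% names(sto)) sto[met] + coef else coef
    }
    lb_ref <- xml_attr_any(node, "lowerFluxBound")
    ub_ref <- xml_attr_any(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref)) pval[[lb_ref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref)) pval[[ub_ref]] else 1000
    rxns[[rid]] <- list(stoichiometry = sto, lower_bound = lb,
                        upper_bound = ub)
  }

  objs <- xml_local(mdl, "objective")
  if (length(objs) > 1) stop("multiple objectives in SBML document")
  if (!length(objs)) stop("no biomass objective in SBML document")
  fo <- xml_local(objs[[1]], "fluxObjective")
  if (length(fo) != 1) stop("no biomass objective in SBML document")
  biomass <- strip_prefix(xml_attr_any(fo[[1]], "reaction"), "R_")

  metabolic_model(xml2::xml_attr(mdl, "id"), mets, rxns, biomass)
}
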