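# SBML Level 3 Version 1 export/import of kinetic models. Kinetic laws are
# written as explicit MathML rate expressions; a machine-readable law
# annotation (in the package's namespace) carries the structured law so that
# import(export(m)) reproduces the model exactly.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
PHK_NS <- "https://phorekin.r-lib.org/law"

mathml_cn <- function(x) sprintf("<cn>%.17g</cn>", x)
mathml_ci <- function(x) sprintf("<ci>%s</ci>", x)

# explicit rate expression of a reaction as MathML
reaction_mathml <- function(r) {
  factors <- character(0)
  if (r$law_type == "mass_action") {
    factors <- c(factors, mathml_cn(r$params$k))
    for (x in r$reactants)
      factors <- c(factors, if (x$stoich == 1L) mathml_ci(x$species) else
        sprintf("<apply><power/>%s%s</apply>", mathml_ci(x$species),
                mathml_cn(x$stoich)))
  } else {
    S <- mathml_ci(r$reactants[[1L]]$species)
    factors <- c(factors,
      sprintf("<apply><divide/><apply><times/>%s%s</apply><apply><plus/>%s%s</apply></apply>",
              mathml_cn(r$params$Vm), S, mathml_cn(r$params$Km), S))
  }
  for (mspec in r$modifiers) factors <- c(factors, mathml_ci(mspec))
  for (inh in r$inhibitors)
    factors <- c(factors,
      sprintf("<apply><divide/><cn>1</cn><apply><plus/><cn>1</cn><apply><divide/>%s%s</apply></apply></apply>",
              mathml_ci(inh$species), mathml_cn(inh$Ki)))
  inner <- if (length(factors) == 1L) factors else
    sprintf("<apply><times/>%s</apply>", paste(factors, collapse = ""))
  sprintf("<math xmlns=\"%s\">%s</math>", MATHML_NS, inner)
}

#' Export a kinetic model to SBML
#'
#' Writes an SBML Level 3 Version 1 document with explicit MathML kinetic
#' laws; a structured law annotation in the package namespace makes the
#' document round-trippable through [import_sbml].
#'
#' @param model A `phk_model`.
#' @param path Optional output path; when NULL an `xml_document` is returned.
#' @return The `xml_document` (invisibly when `path` is given).
#' @export
export_sbml <- function(model, path = NULL) {
  comps <- unique(model$compartments)
  xml <- c(sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"1\">", SBML_NS),
           "<model id=\"phorekin_model\">",
           "<listOfCompartments>",
           sprintf("<compartment id=\"%s\" size=\"1\" constant=\"true\"/>",
                   comps),
           "</listOfCompartments>",
           "<listOfSpecies>")
  for (i in seq_along(model$species))
    xml <- c(xml, sprintf(
      "<species id=\"%s\" compartment=\"%s\" initialConcentration=\"%.17g\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" constant=\"false\"/>",
      model$species[i], model$compartments[i], model$init[[i]]))
  xml <- c(xml, "</listOfSpecies>", "<listOfReactions>")
  for (r in model$reactions) {
    xml <- c(xml, sprintf("<reaction id=\"%s\" reversible=\"false\">", r$id))
    if (length(r$reactants)) {
      xml <- c(xml, "<listOfReactants>",
               vapply(r$reactants, function(x) sprintf(
                 "<speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
                 x$species, x$stoich), character(1)),
               "</listOfReactants>")
    }
    if (length(r$products)) {
      xml <- c(xml, "<listOfProducts>",
               vapply(r$products, function(x) sprintf(
                 "<speciesReference species=\"%s\" stoichiometry=\"%d\" constant=\"true\"/>",
                 x$species, x$stoich), character(1)),
               "</listOfProducts>")
    }
    mods <- c(r$modifiers,
              vapply(r$inhibitors, `[[`, character(1), "species"))
    if (length(mods)) {
      xml <- c(xml, "<listOfModifiers>",
               sprintf("<modifierSpeciesReference species=\"%s\"/>", mods),
               "</listOfModifiers>")
    }
    law_json <- jsonlite::toJSON(list(
      type = r$law_type, params = r$params, modifiers = r$modifiers,
      inhibitors = r$inhibitors), auto_unbox = TRUE, digits = NA)
    xml <- c(xml, "<kineticLaw>",
             sprintf("<annotation><phorekin:law xmlns:phorekin=\"%s\">%s</phorekin:law></annotation>",
                     PHK_NS, gsub("<", "&lt;", as.character(law_json))),
             reaction_mathml(r),
             "</kineticLaw>", "</reaction>")
  }
  xml <- c(xml, "</listOfReactions>", "</model>", "</sbml>")
  doc <- xml2::read_xml(paste(xml, collapse = ""))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import a kinetic model from SBML
#'
#' Reads documents written by [export_sbml] (SBML L3V1 with the package's
#' structured law annotation).
#'
#' @param doc An `xml_document`, SBML string, or file path.
#' @param ligand Optional ligand species name to record on the model.
#' @param readouts Optional readout species (default: any of
#'   `Insulin_secreted`, `cAMP` present).
#' @return A `phk_model`.
#' @export
import_sbml <- function(doc, ligand = NULL, readouts = NULL) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  ns <- c(s = SBML_NS, p = PHK_NS)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- lapply(sp_nodes, function(n) list(
    name = xml2::xml_attr(n, "id"),
    init_um = as.numeric(xml2::xml_attr(n, "initialConcentration")),
    compartment = xml2::xml_attr(n, "compartment")))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(n) {
    rid <- xml2::xml_attr(n, "id")
    side <- function(xp) lapply(xml2::xml_find_all(n, xp, ns), function(sr)
      list(species = xml2::xml_attr(sr, "species"),
           stoich = as.integer(xml2::xml_attr(sr, "stoichiometry"))))
    ann <- xml2::xml_find_first(n, ".//s:kineticLaw/s:annotation/p:law", ns)
    if (inherits(ann, "xml_missing"))
      stop("reaction '", rid, "': no structured kinetic-law annotation")
    law <- jsonlite::fromJSON(xml2::xml_text(ann), simplifyVector = FALSE)
    if (!law$type %in% c("mass_action", "michaelis_menten"))
      stop("reaction '", rid, "': unsupported rate law '", law$type, "'")
    list(id = rid,
         reactants = side("./s:listOfReactants/s:speciesReference"),
         products = side("./s:listOfProducts/s:speciesReference"),
         modifiers = lapply(law$modifiers, as.character),
         inhibitors = law$inhibitors,
         law = list(type = law$type, params = law$params))
  })
  spec <- list(species = species, reactions = reactions,
               readouts = readouts, ligand = ligand)
  if (is.null(spec$readouts)) {
    nm <- vapply(species, `[[`, character(1), "name")
    spec$readouts <- intersect(c("Insulin_secreted", "cAMP"), nm)
  }
  build_model(spec)
}

#' Structurally validate an SBML document
#'
#' Checks well-formedness, the SBML level/version, and that every species
#' and compartment reference resolves to a declared element.
#'
#' @param doc An `xml_document`, SBML string, or file path.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("root element is not <sbml>")
  if (xml2::xml_attr(doc, "level") != "3" ||
      xml2::xml_attr(doc, "version") != "1")
    stop("document is not SBML Level 3 Version 1")
  ns <- c(s = SBML_NS)
  comp_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns),
    "id")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  bad_comp <- setdiff(xml2::xml_attr(sp_nodes, "compartment"), comp_ids)
  if (length(bad_comp))
    stop("species reference undeclared compartments: ",
         paste(bad_comp, collapse = ", "))
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference | .//s:modifierSpeciesReference",
                       ns), "species")
  bad <- setdiff(refs, sp_ids)
  if (length(bad))
    stop("reactions reference undeclared species: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
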