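# SBML Level 3 interchange.
#
# Models are written as standard SBML (species with initial concentrations,
# parameters, reactions with reactants/products/modifiers and a MathML
# kinetic law of the form k * multiplicity * [substrate] * A_modifier).  The
# fractional-occupancy activity expressions and the package's structural
# metadata (shared rate parameters, second-phosphorylation multiplicity,
# inhibitor sensitivity, stress terms, parameter classes and bounds,
# condition definitions) are carried in a package annotation namespace,
# which import uses to reconstruct the model exactly; the round trip
# preserves right-hand-side evaluation to machine precision.  Import of
# arbitrary third-party SBML is not supported.

.MTOR_NS <- "https://r-packages.invalid/mtorStress/sbml"

.mathml_flux <- function(param, mult, substrate, modifier, stress_param) {
  terms <- c(sprintf("<ci> %s </ci>", param),
             if (mult > 1) sprintf("<cn type=\"integer\"> %d </cn>", mult),
             sprintf("<ci> %s </ci>", substrate),
             if (modifier != "none") sprintf("<ci> A_%s </ci>", modifier))
  base <- sprintf("<apply><times/>%s</apply>", paste(terms, collapse = ""))
  if (!is.na(stress_param)) {
    stress <- sprintf(
      "<apply><times/><ci> %s </ci><ci> u_stress </ci><ci> %s </ci></apply>",
      stress_param, substrate)
    base <- sprintf("<apply><plus/>%s%s</apply>", base, stress)
  }
  sprintf("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">%s</math>",
          base)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a model as SBML Level 3
#'
#' @param model An [MTORModel-class] object.
#' @param path Output file path (.xml).
#' @param icCondition Condition label whose initial-concentration block
#'   fills the species' initialConcentration attributes; defaults to the
#'   first condition.
#' @return Invisibly, `path`.
#' @export
exportSBML <- function(model, path,
                       icCondition = names(model@conditions)[1]) {
  stopifnot(is(model, "MTORModel"))
  params <- parameterValues(model)
  y0 <- tryCatch(
    initialState(model, model@conditions[[icCondition]], params),
    error = function(e) stats::setNames(rep(0, 25), model@species))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    "xmlns:mtor" = .MTOR_NS, level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = .sbml_id(paste0("mtor_stress_",
                                                  model@variant)),
                             name = sprintf("stress-mTORC1 model %s",
                                            model@variant))
  ann <- xml2::xml_add_child(mdl, "annotation")
  mann <- xml2::xml_add_child(ann, "mtor:modelInfo",
                              variant = model@variant,
                              sFlag = as.character(model@sFlag),
                              mkExtent = format(model@mkExtent, digits = 17))
  for (cond in model@conditions) {
    xml2::xml_add_child(mann, "mtor:condition", label = cond@label,
                        stress = as.character(cond@stress),
                        wortmannin = as.character(cond@wortmannin),
                        mk2206 = as.character(cond@mk2206),
                        insulin = format(cond@insulin, digits = 17),
                        aa = format(cond@aa, digits = 17),
                        reference = cond@reference,
                        normalizeWith = cond@normalizeWith,
                        icBlock = cond@icBlock)
  }
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (sp in model@species) {
    xml2::xml_add_child(los, "species", id = .sbml_id(sp), name = sp,
                        compartment = "cell",
                        initialConcentration = format(y0[[sp]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  pt <- model@parameters
  for (i in seq_len(nrow(pt))) {
    pn <- xml2::xml_add_child(lop, "parameter", id = .sbml_id(pt$name[i]),
                              name = pt$name[i],
                              value = format(pt$value[i], digits = 17),
                              constant = "true")
    pa <- xml2::xml_add_child(pn, "annotation")
    xml2::xml_add_child(pa, "mtor:paramInfo", klass = pt$klass[i],
                        lower = format(pt$lower[i], digits = 17),
                        upper = format(pt$upper[i], digits = 17),
                        fixed = as.character(pt$fixed[i]))
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  rt <- model@reactions
  for (i in seq_len(nrow(rt))) {
    rx <- xml2::xml_add_child(lor, "reaction",
                              id = sprintf("R%02d", i), reversible = "false")
    ra <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(ra, "mtor:reactionInfo",
                        substrate = rt$substrate[i], product = rt$product[i],
                        param = rt$param[i], modifier = rt$modifier[i],
                        multiplicity = as.character(rt$multiplicity[i]),
                        mkSensitive = as.character(rt$mk_sensitive[i]),
                        wortmanninSensitive =
                          as.character(rt$wortmannin_sensitive[i]),
                        stressParam = ifelse(is.na(rt$stress_param[i]), "",
                                             rt$stress_param[i]))
    lr <- xml2::xml_add_child(rx, "listOfReactants")
    xml2::xml_add_child(lr, "speciesReference",
                        species = .sbml_id(rt$substrate[i]),
                        stoichiometry = "1", constant = "true")
    lp <- xml2::xml_add_child(rx, "listOfProducts")
    xml2::xml_add_child(lp, "speciesReference",
                        species = .sbml_id(rt$product[i]),
                        stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::read_xml(.mathml_flux(rt$param[i], rt$multiplicity[i],
                                        .sbml_id(rt$substrate[i]),
                                        rt$modifier[i], rt$stress_param[i]))
    xml2::xml_add_child(kl, math)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML written by [exportSBML()]
#'
#' @param path SBML file path.
#' @return An [MTORModel-class] object; RHS evaluation agrees with the
#'   exported model to machine precision.
#' @export
importSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          mtor = .MTOR_NS)
  info <- xml2::xml_find_first(doc, ".//mtor:modelInfo", ns)
  if (inherits(info, "xml_missing"))
    stop(sprintf("%s: not an SBML file written by this package (missing %s annotation)",
                 path, "modelInfo"), call. = FALSE)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp <- xml2::xml_attr(sp_nodes, "name")
  if (!identical(sp, speciesNames()))
    stop(sprintf("%s: species list does not match the canonical 25-species network",
                 path), call. = FALSE)
  conds <- lapply(xml2::xml_find_all(info, "./mtor:condition", ns),
                  function(nd) {
    a <- function(x) xml2::xml_attr(nd, x)
    stressCondition(a("label"), stress = as.logical(a("stress")),
                    wortmannin = as.logical(a("wortmannin")),
                    mk2206 = as.logical(a("mk2206")),
                    insulin = as.numeric(a("insulin")),
                    aa = as.numeric(a("aa")), reference = a("reference"),
                    normalizeWith = a("normalizeWith"),
                    icBlock = a("icBlock"))
  })
  names(conds) <- vapply(conds, function(x) x@label, character(1))
  p_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pt <- do.call(rbind, lapply(p_nodes, function(nd) {
    pa <- xml2::xml_find_first(nd, ".//mtor:paramInfo", ns)
    data.frame(name = xml2::xml_attr(nd, "name"),
               value = as.numeric(xml2::xml_attr(nd, "value")),
               klass = xml2::xml_attr(pa, "klass"),
               lower = as.numeric(xml2::xml_attr(pa, "lower")),
               upper = as.numeric(xml2::xml_attr(pa, "upper")),
               fixed = as.logical(xml2::xml_attr(pa, "fixed")),
               stringsAsFactors = FALSE)
  }))
  r_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rt <- do.call(rbind, lapply(r_nodes, function(nd) {
    ra <- xml2::xml_find_first(nd, ".//mtor:reactionInfo", ns)
    a <- function(x) xml2::xml_attr(ra, x)
    data.frame(substrate = a("substrate"), product = a("product"),
               param = a("param"), modifier = a("modifier"),
               multiplicity = as.integer(a("multiplicity")),
               mk_sensitive = as.logical(a("mkSensitive")),
               wortmannin_sensitive = as.logical(a("wortmanninSensitive")),
               stress_param = ifelse(nzchar(a("stressParam")),
                                     a("stressParam"), NA_character_),
               stringsAsFactors = FALSE)
  }))
  new("MTORModel",
      variant = xml2::xml_attr(info, "variant"), species = sp,
      pools = conservationPools(), reactions = rt, parameters = pt,
      sFlag = as.logical(xml2::xml_attr(info, "sFlag")),
      mkExtent = as.numeric(xml2::xml_attr(info, "mkExtent")),
      conditions = conds)
}
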