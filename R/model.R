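# Reaction network shared by all model variants.
#
# One row per substrate -> product conversion. `param` is the (possibly
# shared) mass-action rate constant; `modifier` names the catalysing activity
# ("none" = plain first-order conversion, i.e. dephosphorylation or reverse
# translocation); `multiplicity` = 2 marks a second phosphorylation, whose
# flux runs at twice the shared first-phosphorylation rate constant;
# `mk_sensitive` marks Akt-catalysed fluxes (scaled by 1 - 0.83 under
# MK-2206); `wortmannin_sensitive` marks the PI3K activation flux (zeroed,
# including its stress term, under wortmannin); `stress_param` is filled per
# variant / input-search candidate.
.reactionRows <- function() {
  R <- function(sub, prod, param, modifier = "none", mult = 1L,
                mk = FALSE, wort = FALSE)
    data.frame(substrate = sub, product = prod, param = param,
               modifier = modifier, multiplicity = mult,
               mk_sensitive = mk, wortmannin_sensitive = wort,
               stress_param = NA_character_, stringsAsFactors = FALSE)
  rbind(
    R("Akt",                "Akt_pS473",           "k_S473_phos",  "mTORC2"),
    R("Akt_pT308",          "Akt_pT308_pS473",     "k_S473_phos",  "mTORC2", 2L),
    R("PDK1_cyt",           "PDK1_mem",            "k_PDK1_mem",   "PI3K"),
    R("Akt",                "Akt_pT308",           "k_T308_phos",  "PDK1"),
    R("TSC2",               "TSC2_pT1462",         "k_TSC2_phos",  "Akt", 1L, TRUE),
    R("PRAS40",             "PRAS40_pT246",        "k_T246_phos",  "Akt", 1L, TRUE),
    R("PRAS40",             "PRAS40_pS183",        "k_S183_phos",  "mTORC1"),
    R("p70_S6K",            "p70_S6K_pT389",       "k_T389_phos",  "mTORC1"),
    R("PRAS40_pS183",       "PRAS40_pT246_pS183",  "k_T246_phos",  "Akt", 2L, TRUE),
    R("p70_S6K",            "p70_S6K_pT229",       "k_T229_phos",  "PDK1"),
    R("IR_beta",            "IR_beta_pY1146",      "k_IR_phos",    "insulin"),
    R("IRS1",               "IRS1_loc_pS636",      "k_IRS1_pS636_direct", "S6K"),
    R("IRS1",               "IRS1_loc",            "k_IRS1_loc",   "IR"),
    R("4EBP1",              "4EBP1_pT37_46",       "k_4EBP1_phos", "mTORC1"),
    R("PRAS40_pS183",       "PRAS40",              "k_S183_dephos"),
    R("p70_S6K_pT229",      "p70_S6K_pT229_pT389", "k_T389_phos",  "mTORC1", 2L),
    R("p70_S6K_pT389",      "p70_S6K_pT229_pT389", "k_T229_phos",  "PDK1", 2L),
    R("Akt_pT308_pS473",    "Akt_pT308",           "k_S473_dephos"),
    R("Akt_pT308_pS473",    "Akt_pS473",           "k_T308_dephos"),
    R("PRAS40_pT246",       "PRAS40_pT246_pS183",  "k_S183_phos",  "mTORC1", 2L),
    R("IRS1_loc",           "IRS1_loc_pS636",      "k_IRS1_pS636_loc", "S6K"),
    R("TSC2_pT1462",        "TSC2",                "k_TSC2_dephos"),
    R("PI3K_p",             "PI3K",                "k_PI3K_dephos"),
    R("PDK1_mem",           "PDK1_cyt",            "k_PDK1_cyt"),
    R("p70_S6K_pT229",      "p70_S6K",             "k_T229_dephos"),
    R("IR_beta_pY1146",     "IR_beta",             "k_IR_dephos"),
    R("Akt_pS473",          "Akt_pT308_pS473",     "k_T308_phos",  "PDK1", 2L),
    R("PRAS40_pT246",       "PRAS40",              "k_T246_dephos"),
    R("PRAS40_pT246_pS183", "PRAS40_pS183",        "k_T246_dephos"),
    R("4EBP1_pT37_46",      "4EBP1",               "k_4EBP1_dephos"),
    R("PRAS40_pT246_pS183", "PRAS40_pT246",        "k_S183_dephos"),
    R("p70_S6K_pT229_pT389","p70_S6K_pT389",       "k_T229_dephos"),
    R("Akt_pS473",          "Akt",                 "k_S473_dephos"),
    R("Akt_pT308",          "Akt",                 "k_T308_dephos"),
    R("IRS1_loc_pS636",     "IRS1",                "k_IRS1_pS636_dephos"),
    R("p70_S6K_pT389",      "p70_S6K",             "k_T389_dephos"),
    R("p70_S6K_pT229_pT389","p70_S6K_pT229",       "k_T389_dephos"),
    R("PI3K",               "PI3K_p",              "k_PI3K_act",   "IRS1",
      1L, FALSE, TRUE)
  )
}

# rate constants of reactions whose flux is structurally zero under the
# serum-starved design (insulin = 0, hence IR_beta_pY1146 = 0 throughout);
# they are present but fixed, not fitted
.DEAD_PARAMS <- c("k_IR_phos", "k_IRS1_loc")

.VARIANTS <- c("I", "II", "III", "IV", "V")

.variantFlags <- function(tag) {
  switch(tag,
    I   = list(pi3k = FALSE, s473 = FALSE, mtorc1 = FALSE, sFlag = TRUE),
    II  = list(pi3k = TRUE,  s473 = FALSE, mtorc1 = FALSE, sFlag = TRUE),
    III = list(pi3k = TRUE,  s473 = TRUE,  mtorc1 = FALSE, sFlag = TRUE),
    IV  = list(pi3k = TRUE,  s473 = TRUE,  mtorc1 = FALSE, sFlag = FALSE),
    V   = list(pi3k = TRUE,  s473 = TRUE,  mtorc1 = TRUE,  sFlag = FALSE))
}

.klassBounds <- function(klass) {
  switch(klass,
    mass_action           = c(-5, 1),
    pi3k_activation       = c(-5, -2),
    initial_concentration = c(-5, 1),
    input_strength        = c(-5, 3),
    fraction              = c(-5, 0),
    generic               = c(-5, 3))
}

.paramRow <- function(name, klass, value = NULL, fixed = FALSE) {
  b <- .klassBounds(klass)
  if (is.null(value)) value <- 10^mean(b)
  data.frame(name = name, value = value, klass = klass,
             lower = b[1], upper = b[2], fixed = fixed,
             stringsAsFactors = FALSE)
}

# kinetic + input parameter table for a given variant
.kineticParams <- function(flags) {
  rt <- .reactionRows()
  kin <- unique(rt$param)
  rows <- do.call(rbind, lapply(kin, function(p) {
    klass <- if (p == "k_PI3K_act") "pi3k_activation" else "mass_action"
    .paramRow(p, klass, fixed = p %in% .DEAD_PARAMS)
  }))
  rows <- rbind(rows, .paramRow("k_aa", "input_strength"))
  if (flags$pi3k)
    rows <- rbind(rows, .paramRow("k_stress_PI3K", "pi3k_activation"))
  if (flags$s473)
    rows <- rbind(rows, .paramRow("k_stress_Akt_S473", "input_strength"))
  if (flags$mtorc1)
    rows <- rbind(rows, .paramRow("k_stress_mTORC1", "input_strength"))
  rows
}

# condition-specific initial-concentration parameter block; conditions that
# borrow another block (no-stress companions) contribute none
.initialParams <- function(condition) {
  if (nzchar(condition@icBlock) && condition@icBlock != condition@label)
    return(NULL)
  lab <- condition@label
  free_sp <- setdiff(speciesNames(), .MTOR_ZERO_INITIAL)
  rows <- do.call(rbind, lapply(free_sp, function(sp) {
    if (sp == "Akt_pT308" && nzchar(condition@reference))
      .paramRow(sprintf("ic_frac_Akt_pT308.%s", lab), "fraction")
    else
      .paramRow(sprintf("ic_%s.%s", sp, lab), "initial_concentration")
  }))
  rows
}

#' Build a model variant
#'
#' Constructs the full 25-species network as one of the five nested variants:
#' \describe{
#'   \item{I}{no stress input (nutritional inputs only).}
#'   \item{II}{stress input on PI3K activation.}
#'   \item{III}{stress inputs on PI3K and on Akt S473 phosphorylation.}
#'   \item{IV}{as III, but Akt phosphorylated at S473 alone is not active
#'     towards the mTORC1 inhibitors TSC2/PRAS40 (only pT308 and
#'     pT308+pS473 species are).}
#'   \item{V}{as IV plus a third stress input acting directly on mTORC1.}
#' }
#' The reaction set is identical across variants; only the stress-term
#' attachments and the Akt activity definition differ.
#'
#' @param variant One of "I", "II", "III", "IV", "V".
#' @param conditions Named list of [StressCondition-class] objects; each
#'   contributes a condition-specific initial-concentration parameter block.
#'   Defaults to the three calibration conditions ([defaultConditions()]).
#' @return An [MTORModel-class] object.
#' @export
#' @examples
#' m <- buildModel("V")
#' length(speciesNames(m))   # 25
#' nFreeParameters(m)        # 91
buildModel <- function(variant = c("I", "II", "III", "IV", "V"),
                       conditions = defaultConditions()) {
  if (length(variant) != 1L || !variant %in% .VARIANTS)
    stop(sprintf("unknown model variant '%s'; valid tags: %s",
                 paste(variant, collapse = ","),
                 paste(.VARIANTS, collapse = ", ")), call. = FALSE)
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, function(x) x@label, character(1))
  flags <- .variantFlags(variant)
  rt <- .reactionRows()
  if (flags$pi3k)
    rt$stress_param[rt$param == "k_PI3K_act"] <- "k_stress_PI3K"
  if (flags$s473)
    rt$stress_param[rt$substrate == "Akt" & rt$product == "Akt_pS473"] <-
      "k_stress_Akt_S473"
  pt <- rbind(.kineticParams(flags),
              do.call(rbind, lapply(conditions, .initialParams)))
  rownames(pt) <- NULL
  new("MTORModel", variant = variant, species = speciesNames(),
      pools = conservationPools(), reactions = rt, parameters = pt,
      sFlag = flags$sFlag, mkExtent = 0.83, conditions = conditions)
}

#' Variant tag of a model
#' @param model An [MTORModel-class] object.
#' @export
modelVariant <- function(model) model@variant

#' Reaction table of a model
#' @param model An [MTORModel-class] object.
#' @return data.frame with one row per reaction.
#' @export
reactionTable <- function(model) model@reactions

#' Parameter table of a model
#' @param model An [MTORModel-class] object.
#' @return data.frame with columns name, value, klass, lower (log10),
#'   upper (log10), fixed.
#' @export
parameterTable <- function(model) model@parameters

#' Number of free parameters of a model
#'
#' Free = not structurally dead and not explicitly fixed: the fitted kinetic
#' rate constants, the input strengths, and all condition-specific
#' initial-concentration parameters. For variant V with the three calibration
#' conditions this totals 91.
#' @param model An [MTORModel-class] object.
#' @export
nFreeParameters <- function(model) sum(!model@parameters$fixed)

#' Names of the free parameters
#' @param model An [MTORModel-class] object.
#' @export
freeParameterNames <- function(model)
  model@parameters$name[!model@parameters$fixed]

#' Default parameter vector of a model
#'
#' The `value` column of the parameter table as a named vector, in table
#' order. Used as the baseline that [chi2Objective()] overwrites with the
#' free parameters under optimization.
#' @param model An [MTORModel-class] object.
#' @export
parameterValues <- function(model) {
  stats::setNames(model@parameters$value, model@parameters$name)
}

#' Replace parameter values
#'
#' @param model An [MTORModel-class] object.
#' @param values Named numeric vector; names must exist in the parameter
#'   table. Values are on the natural (not log10) scale.
#' @return The updated model.
#' @export
setParameterValues <- function(model, values) {
  pt <- model@parameters
  bad <- setdiff(names(values), pt$name)
  if (length(bad))
    stop("unknown parameters: ", paste(bad, collapse = ", "), call. = FALSE)
  pt$value[match(names(values), pt$name)] <- unname(values)
  model@parameters <- pt
  validObject(model)
  model
}

#' Enumerate candidate reactions for a second stress input
#'
#' Every substrate -> product conversion of the network that can receive an
#' additional arsenite input, in canonical order: all 37 conversions except
#' the PI3K activation step, which already carries the first stress input in
#' variant II.
#'
#' @param model An [MTORModel-class] object of variant II (one stress input).
#' @return data.frame with columns substrate, product.
#' @export
#' @examples
#' nrow(candidateStressTargets(buildModel("II")))  # 37
candidateStressTargets <- function(model) {
  stopifnot(is(model, "MTORModel"))
  n_inputs <- sum(!is.na(model@reactions$stress_param)) +
    ("k_stress_mTORC1" %in% model@parameters$name)
  if (n_inputs >= 2L)
    stop("model already carries ", n_inputs,
         " stress inputs; candidate enumeration is defined for the ",
         "single-input model II", call. = FALSE)
  rt <- model@reactions
  cand <- rt[rt$param != "k_PI3K_act", c("substrate", "product")]
  rownames(cand) <- NULL
  cand
}

#' Attach an additional stress input to a model
#'
#' Returns a new model in which the targeted reaction carries an arsenite
#' stress term with a fresh input-strength parameter (flux
#' `k_stress * u_stress(t) * [substrate]`). The special target "mTORC1"
#' attaches the stress term to the implicit mTORC1 activity instead (the
#' third input of model V). The input model is unchanged; the free-parameter
#' count grows by exactly one.
#'
#' @param model An [MTORModel-class] object.
#' @param substrate,product Species names identifying the target reaction
#'   from [candidateStressTargets()]; or `substrate = "mTORC1"` (and
#'   `product` missing) for the implicit-complex target.
#' @return A new [MTORModel-class] object.
#' @export
#' @examples
#' m3 <- withStressInput(buildModel("II"), "Akt", "Akt_pS473")
#' nFreeParameters(m3) - nFreeParameters(buildModel("II"))  # 1
withStressInput <- function(model, substrate, product) {
  stopifnot(is(model, "MTORModel"))
  if (identical(substrate, "mTORC1")) {
    if ("k_stress_mTORC1" %in% model@parameters$name)
      stop("model already carries a stress input on mTORC1", call. = FALSE)
    model@parameters <- rbind(model@parameters,
                              .paramRow("k_stress_mTORC1", "input_strength"))
    model@variant <- paste0(model@variant, "+mTORC1")
    validObject(model)
    return(model)
  }
  rt <- model@reactions
  hit <- which(rt$substrate == substrate & rt$product == product)
  if (length(hit) != 1L)
    stop(sprintf("no reaction %s -> %s in the network", substrate, product),
         call. = FALSE)
  if (rt$param[hit] == "k_PI3K_act")
    stop("the PI3K activation step already carries the first stress input",
         call. = FALSE)
  if (!is.na(rt$stress_param[hit]))
    stop(sprintf("reaction %s -> %s already carries a stress input",
                 substrate, product), call. = FALSE)
  pname <- sprintf("k_stress_%s_to_%s", substrate, product)
  rt$stress_param[hit] <- pname
  model@reactions <- rt
  model@parameters <- rbind(model@parameters,
                            .paramRow(pname, "input_strength"))
  model@variant <- paste0(model@variant, "+", substrate, ">", product)
  validObject(model)
  model
}

#' Plain-text model summary
#'
#' Prints the species table (with pool membership), the reaction table and
#' the parameter table with bounds and class.
#' @param model An [MTORModel-class] object.
#' @param file Optional path; if given the summary is written there.
#' @return Invisibly, the summary as a character vector of lines.
#' @export
modelSummary <- function(model, file = NULL) {
  pidx <- .poolIndex()
  sp <- data.frame(species = model@species,
                   pool = names(model@pools)[pidx[model@species]])
  lines <- c(
    sprintf("mTOR stress model, variant %s (%d species, %d reactions, %d free parameters)",
            model@variant, length(model@species), nrow(model@reactions),
            nFreeParameters(model)),
    "", "== Species ==", utils::capture.output(print(sp)),
    "", "== Reactions ==", utils::capture.output(print(model@reactions)),
    "", "== Parameters ==", utils::capture.output(print(model@parameters)))
  if (!is.null(file)) writeLines(lines, file) else writeLines(lines)
  invisible(lines)
}

#' @export
setMethod("show", "MTORModel", function(object) {
  n_stress <- sum(!is.na(object@reactions$stress_param)) +
    ("k_stress_mTORC1" %in% object@parameters$name)
  cat(sprintf("MTORModel variant %s\n", object@variant))
  cat(sprintf("  %d species in %d conserved pools, %d reactions\n",
              length(object@species), length(object@pools),
              nrow(object@reactions)))
  cat(sprintf("  %d parameters (%d free), %d stress input(s)\n",
              nrow(object@parameters), nFreeParameters(object), n_stress))
  cat(sprintf("  conditions: %s\n",
              paste(names(object@conditions), collapse = ", ")))
  cat(sprintf("  Akt-pS473 alone active towards mTORC1 inhibitors: %s\n",
              object@sFlag))
})
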