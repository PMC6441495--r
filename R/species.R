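#' Canonical species of the stress-mTORC1 network
#'
#' The network tracks nine signaling proteins, each as a conserved pool of
#' phosphorylation / localization variants: the insulin receptor beta chain
#' (IR_beta), IRS1 (cytosolic, membrane-localized, and S6K-phosphorylated),
#' PI3K (inactive/active), PDK1 (cytosolic/membrane), Akt (four phospho-states
#' over T308 and S473), TSC2, PRAS40 (four phospho-states over T246 and S183),
#' p70-S6K (four phospho-states over T229 and T389), and 4E-BP1. The mTOR
#' complexes mTORC1 and mTORC2 are represented implicitly through the fluxes
#' they catalyse, not as dynamic species.
#'
#' All state vectors, trajectories and right-hand-side evaluations in the
#' package use this fixed ordering.
#'
#' @param model Optionally an [MTORModel-class] object; its (identical)
#'   species vector is returned.
#' @return Character vector of the 25 species names in canonical order.
#' @export
#' @examples
#' speciesNames()
speciesNames <- function(model) {
  if (!missing(model) && is(model, "MTORModel")) return(model@species)
  .MTOR_SPECIES
}

.MTOR_SPECIES <- c(
  "IR_beta", "IR_beta_pY1146",
  "IRS1", "IRS1_loc", "IRS1_loc_pS636",
  "PI3K", "PI3K_p",
  "PDK1_cyt", "PDK1_mem",
  "Akt", "Akt_pT308", "Akt_pS473", "Akt_pT308_pS473",
  "TSC2", "TSC2_pT1462",
  "PRAS40", "PRAS40_pT246", "PRAS40_pS183", "PRAS40_pT246_pS183",
  "p70_S6K", "p70_S6K_pT229", "p70_S6K_pT389", "p70_S6K_pT229_pT389",
  "4EBP1", "4EBP1_pT37_46"
)

# double-phosphorylated species: initial concentration fixed to zero
.MTOR_DOUBLE_PHOSPHO <- c("Akt_pT308_pS473", "PRAS40_pT246_pS183",
                          "p70_S6K_pT229_pT389")

# species whose initial concentration is structurally zero under overnight
# serum starvation (no insulin drive ever raises it)
.MTOR_ZERO_INITIAL <- c(.MTOR_DOUBLE_PHOSPHO, "IR_beta_pY1146")

.MTOR_POOLS <- list(
  IR      = c("IR_beta", "IR_beta_pY1146"),
  IRS1    = c("IRS1", "IRS1_loc", "IRS1_loc_pS636"),
  PI3K    = c("PI3K", "PI3K_p"),
  PDK1    = c("PDK1_cyt", "PDK1_mem"),
  Akt     = c("Akt", "Akt_pT308", "Akt_pS473", "Akt_pT308_pS473"),
  TSC2    = c("TSC2", "TSC2_pT1462"),
  PRAS40  = c("PRAS40", "PRAS40_pT246", "PRAS40_pS183", "PRAS40_pT246_pS183"),
  p70_S6K = c("p70_S6K", "p70_S6K_pT229", "p70_S6K_pT389",
              "p70_S6K_pT229_pT389"),
  `4EBP1` = c("4EBP1", "4EBP1_pT37_46")
)

#' Conserved pools of the network
#'
#' Each protein's phosphorylation/localization variants form a conserved
#' moiety: their summed concentration is constant along any trajectory
#' (no synthesis or degradation on the 0-60 min timescale). The nine pools
#' partition the 25 species.
#'
#' @return Named list; each element is the character vector of member species.
#' @export
#' @examples
#' conservationPools()$Akt
conservationPools <- function() .MTOR_POOLS

# pool index (1..9) for each species, in canonical species order
.poolIndex <- function() {
  idx <- integer(length(.MTOR_SPECIES))
  names(idx) <- .MTOR_SPECIES
  for (p in seq_along(.MTOR_POOLS)) idx[.MTOR_POOLS[[p]]] <- p
  idx
}

#' Immunoblot observables
#'
#' The nine phospho-readouts quantified in the calibration datasets. Each
#' observable is the summed concentration of every species carrying the
#' phosphosite, e.g. the Akt-pS473 signal is \[Akt_pS473\] +
#' \[Akt_pT308_pS473\], because an antibody against one site does not
#' discriminate the other site's state.
#'
#' @return Named list mapping observable name to its summand species.
#' @export
#' @examples
#' observableDefs()[["Akt_pS473"]]
observableDefs <- function() .MTOR_OBSERVABLES

.MTOR_OBSERVABLES <- list(
  Akt_pT308     = c("Akt_pT308", "Akt_pT308_pS473"),
  Akt_pS473     = c("Akt_pS473", "Akt_pT308_pS473"),
  TSC2_pT1462   = "TSC2_pT1462",
  PRAS40_pS183  = c("PRAS40_pS183", "PRAS40_pT246_pS183"),
  PRAS40_pT246  = c("PRAS40_pT246", "PRAS40_pT246_pS183"),
  p70_S6K_pT389 = c("p70_S6K_pT389", "p70_S6K_pT229_pT389"),
  p70_S6K_pT229 = c("p70_S6K_pT229", "p70_S6K_pT229_pT389"),
  `4EBP1_pT37_46` = "4EBP1_pT37_46",
  IRS1_pS636    = "IRS1_loc_pS636"
)
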