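# Pinned synthetic ground truth.
#
# One documented parameter regime for model V under the three calibration
# conditions, chosen once so that the synthetic study reproduces the
# qualitative physiology of the arsenite response: at least two-fold stress
# induction of Akt-pT308, Akt-pS473, TSC2-pT1462 and p70-S6K-pT389 by 30-60
# min, and under wortmannin a residual (PI3K-independent) stress induction
# of Akt-pS473 and p70-S6K-pT389 at reduced amplitude.  PI3K activation
# rates respect the tight pi3k_activation bounds (<= 1e-2 per min), making
# the PI3K arm the slow upstream timescale.  All recovery and search
# experiments in the package target this vector.

.GT_KINETIC <- c(
  k_S473_phos         = 2.0,    # mTORC2-driven S473 phosphorylation
  k_PDK1_mem          = 2.0,    # PI3K-driven PDK1 membrane translocation
  k_T308_phos         = 0.6,    # PDK1-driven T308 phosphorylation
  k_TSC2_phos         = 1.0,    # Akt-driven TSC2 T1462 phosphorylation
  k_T246_phos         = 0.8,    # Akt-driven PRAS40 T246
  k_S183_phos         = 1.0,    # mTORC1-driven PRAS40 S183
  k_T389_phos         = 1.5,    # mTORC1-driven S6K T389
  k_T229_phos         = 0.5,    # PDK1-driven S6K T229
  k_IR_phos           = 1e-5,   # structurally dead (insulin = 0), fixed
  k_IRS1_pS636_direct = 0.05,   # S6K feedback, cytosolic IRS1
  k_IRS1_loc          = 1e-5,   # structurally dead (IR never active), fixed
  k_4EBP1_phos        = 1.0,
  k_S183_dephos       = 0.3,
  k_S473_dephos       = 1.0,
  k_T308_dephos       = 0.8,
  k_IRS1_pS636_loc    = 0.01,
  k_TSC2_dephos       = 0.25,
  k_PI3K_dephos       = 0.03,
  k_PDK1_cyt          = 0.4,
  k_T229_dephos       = 0.6,
  k_IR_dephos         = 0.1,
  k_T246_dephos       = 0.4,
  k_4EBP1_dephos      = 0.5,
  k_IRS1_pS636_dephos = 0.08,
  k_T389_dephos       = 0.8,
  k_PI3K_act          = 0.004,  # basal IRS1-driven PI3K activation
  k_aa                = 1.5,    # amino-acid drive of mTORC1
  k_stress_PI3K       = 0.01,   # stress input 1 (slow, bounded at 1e-2)
  k_stress_Akt_S473   = 0.4,    # stress input 2 (PI3K-independent)
  k_stress_mTORC1     = 4.0     # stress input 3 (direct mTORC1)
)

# starved-baseline initials per condition (a.u.; pools total about 1).
# The arsenite block is the model's own relaxed no-stress state (overnight
# starvation represented as a settled baseline), so the artificial no-stress
# companion datasets are nearly constant at the truth.  The inhibitor blocks
# are that baseline integrated for a further 30 min with the inhibitor
# present: the pre-incubation of the experimental design absorbed into the
# condition-specific initials.  Double-phosphorylated species are started at
# zero by construction.
.GT_IC <- list(
  arsenite = c(
    IR_beta = 1, IRS1 = 0.8516, IRS1_loc = 0.0923, IRS1_loc_pS636 = 0.056,
    PI3K = 0.9873, PI3K_p = 0.0127, PDK1_cyt = 0.9404, PDK1_mem = 0.0596,
    Akt = 0.9325, Akt_pT308 = 0.0418, Akt_pS473 = 0.0236,
    TSC2 = 0.8441, TSC2_pT1462 = 0.1559,
    PRAS40 = 0.7599, PRAS40_pT246 = 0.0702, PRAS40_pS183 = 0.1435,
    p70_S6K = 0.8576, p70_S6K_pT229 = 0.0427, p70_S6K_pT389 = 0.0906,
    `4EBP1` = 0.8985, `4EBP1_pT37_46` = 0.1015),
  # 30 min wortmannin pre-treatment; Akt_pT308 is fraction-encoded relative
  # to the arsenite-specific initial
  arsenite_wortmannin = c(
    IR_beta = 1, IRS1 = 0.8793, IRS1_loc = 0.0905, IRS1_loc_pS636 = 0.0301,
    PI3K = 0.9948, PI3K_p = 0.0052, PDK1_cyt = 0.9729, PDK1_mem = 0.0271,
    Akt = 0.9668, Akt_pS473 = 0.0103,
    TSC2 = 0.9131, TSC2_pT1462 = 0.0869,
    PRAS40 = 0.8813, PRAS40_pT246 = 0.0407, PRAS40_pS183 = 0.0472,
    p70_S6K = 0.9432, p70_S6K_pT229 = 0.0224, p70_S6K_pT389 = 0.0241,
    `4EBP1` = 0.9719, `4EBP1_pT37_46` = 0.0281),
  # 30 min MK-2206 pre-treatment: Akt substrates (TSC2-pT1462,
  # PRAS40-pT246) and mTORC1 readouts settle lower
  arsenite_mk2206 = c(
    IR_beta = 1, IRS1 = 0.9, IRS1_loc = 0.0919, IRS1_loc_pS636 = 0.008,
    PI3K = 0.9877, PI3K_p = 0.0123, PDK1_cyt = 0.9418, PDK1_mem = 0.0582,
    Akt = 0.9321, Akt_pT308 = 0.0407, Akt_pS473 = 0.023,
    TSC2 = 0.9703, TSC2_pT1462 = 0.0297,
    PRAS40 = 0.9562, PRAS40_pT246 = 0.0146, PRAS40_pS183 = 0.0027,
    p70_S6K = 0.9435, p70_S6K_pT229 = 0.0458, p70_S6K_pT389 = 0.0014,
    `4EBP1` = 0.9984, `4EBP1_pT37_46` = 0.0016)
)

.GT_WORT_FRACTION <- 0.49  # Akt_pT308(wortmannin, 0) / Akt_pT308(arsenite, 0)

#' Pinned ground-truth parameter vector
#'
#' The documented synthetic-truth regime for model V with the three
#' calibration conditions: all kinetic rate constants, input strengths and
#' condition-specific initial concentrations as one named vector matching
#' `parameterTable(buildModel("V"))`. This vector generates the package's
#' synthetic study and is the recovery target of the calibration tests.
#'
#' @param variant Model variant whose parameter set to return (stress
#'   strengths absent from the variant are dropped). Default "V".
#' @return Named numeric vector on the natural scale.
#' @export
#' @examples
#' p <- groundTruthParams()
#' p[["k_stress_PI3K"]]
groundTruthParams <- function(variant = "V") {
  model <- buildModel(variant)
  want <- model@parameters$name
  ic <- unlist(lapply(names(.GT_IC), function(lab) {
    v <- .GT_IC[[lab]]
    stats::setNames(v, sprintf("ic_%s.%s", names(v), lab))
  }))
  ic <- c(ic, stats::setNames(.GT_WORT_FRACTION,
                              "ic_frac_Akt_pT308.arsenite_wortmannin"))
  # drop the explicit wortmannin Akt_pT308 initial: it is fraction-encoded
  ic <- ic[names(ic) != "ic_Akt_pT308.arsenite_wortmannin"]
  full <- c(.GT_KINETIC, ic)
  miss <- setdiff(want, names(full))
  if (length(miss))
    stop("ground truth incomplete for: ", paste(miss, collapse = ", "))
  full[want]
}

#' Generate the pinned synthetic calibration study
#'
#' The three-condition synthetic study (arsenite, arsenite + wortmannin,
#' arsenite + MK-2206) generated from the ground-truth vector, optionally
#' with the artificial no-stress companion datasets appended.
#'
#' @param model Generating model; default `buildModel("V")` (data generated
#'   from a different variant's truth are obtained by passing that model and
#'   its parameter subset).
#' @param params Generating parameter vector; default [groundTruthParams()].
#' @param times,nReps,cv,seed,normalize Passed to [generateDataset()].
#' @param companions Append [makeConstantDataset()] companions (default
#'   TRUE).
#' @param conditions Conditions to include; default all three.
#' @return A [TimeCourseDataset-class] object.
#' @export
syntheticStudy <- function(model = buildModel("V"),
                           params = groundTruthParams(modelVariant(model)),
                           times = defaultTimes(), nReps = 4, cv = 0.15,
                           seed = 1, normalize = TRUE, companions = TRUE,
                           conditions = model@conditions) {
  ds <- generateDataset(model, params, conditions, times = times,
                        nReps = nReps, cv = cv, seed = seed,
                        normalize = normalize)
  if (companions) ds <- bindDatasets(ds, makeConstantDataset(ds))
  ds
}
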