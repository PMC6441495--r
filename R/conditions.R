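#' Construct an experimental condition
#'
#' @param label Dataset label keying the condition-specific
#'   initial-concentration parameter block.
#' @param stress Logical; arsenite stress applied as a unit step at t = 0.
#' @param wortmannin Logical; PI3K activation flux fully suppressed.
#' @param mk2206 Logical; Akt activity scaled by (1 - 0.83).
#' @param insulin,aa Input levels. The calibration design is serum-starved
#'   (insulin 0) in full medium (amino acids 1).
#' @param reference Label of the condition whose Akt_pT308 initial anchors
#'   this condition's fraction parameter, or "" (used for wortmannin
#'   pre-treatment, which lowers the Akt_pT308 baseline).
#' @param normalizeWith Label of the parent condition providing the
#'   normalization factors in the objective, or "" for self-normalization.
#'   Set automatically for artificial no-stress companions.
#' @return A [StressCondition-class] object.
#' @export
#' @examples
#' stressCondition("arsenite", stress = TRUE)
stressCondition <- function(label, stress = TRUE, wortmannin = FALSE,
                            mk2206 = FALSE, insulin = 0, aa = 1,
                            reference = "", normalizeWith = "",
                            icBlock = "") {
  new("StressCondition", label = label, stress = stress,
      wortmannin = wortmannin, mk2206 = mk2206, insulin = insulin, aa = aa,
      reference = reference, normalizeWith = normalizeWith,
      icBlock = icBlock)
}

#' The three calibration conditions
#'
#' Arsenite, arsenite + wortmannin and arsenite + MK-2206, each with its own
#' initial-concentration parameter block. The wortmannin condition's
#' Akt_pT308 initial is expressed as a fraction of the arsenite-specific
#' initial (30 min pre-incubation suppresses the PI3K-PDK1 axis before
#' stress is applied).
#'
#' @return Named list of [StressCondition-class] objects.
#' @export
defaultConditions <- function() {
  conds <- list(
    stressCondition("arsenite"),
    stressCondition("arsenite_wortmannin", wortmannin = TRUE,
                    reference = "arsenite"),
    stressCondition("arsenite_mk2206", mk2206 = TRUE)
  )
  names(conds) <- vapply(conds, function(x) x@label, character(1))
  conds
}

#' Derive the no-stress companion of a condition
#'
#' Same inhibitor flags and initial-concentration block, but no arsenite
#' input; in the objective its simulation is normalized with the parent
#' condition's factors.
#'
#' @param condition A [StressCondition-class] object.
#' @return A [StressCondition-class] with stress off and a `_no_stress`
#'   label suffix.
#' @export
noStressCompanion <- function(condition) {
  stopifnot(is(condition, "StressCondition"))
  new("StressCondition",
      label = paste0(condition@label, "_no_stress"), stress = FALSE,
      wortmannin = condition@wortmannin, mk2206 = condition@mk2206,
      insulin = condition@insulin, aa = condition@aa,
      reference = condition@reference, normalizeWith = condition@label,
      icBlock = if (nzchar(condition@icBlock)) condition@icBlock
                else condition@label)
}

#' @export
setMethod("show", "StressCondition", function(object) {
  inh <- c(if (object@wortmannin) "wortmannin", if (object@mk2206) "MK-2206")
  cat(sprintf("StressCondition '%s': stress=%s, inhibitors=%s, insulin=%g, aa=%g\n",
              object@label, object@stress,
              if (length(inh)) paste(inh, collapse = "+") else "none",
              object@insulin, object@aa))
})
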