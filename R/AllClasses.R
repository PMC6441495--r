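#' @import methods
NULL

#' MTORModel: a concrete reaction-network instance
#'
#' One of the five model variants (I-V), optionally augmented with additional
#' candidate stress inputs. Holds the 25 species in canonical order, the
#' conserved pools, the reaction table (substrate, product, shared rate
#' parameter, catalysing activity, second-phosphorylation multiplicity,
#' inhibitor sensitivity, attached stress-input parameter), the parameter
#' table with values, log10 bounds, class and fixed/free status, and the
#' condition set whose labels key the condition-specific initial-concentration
#' parameter blocks.
#'
#' @slot variant character; "I".."V", possibly with an input-augmentation
#'   suffix such as "II+Akt>Akt_pS473".
#' @slot species character(25), canonical species order.
#' @slot pools named list partitioning the species into conserved moieties.
#' @slot reactions data.frame reaction table (see [reactionTable()]).
#' @slot parameters data.frame parameter table (see [parameterTable()]).
#' @slot sFlag logical; TRUE if Akt phosphorylated at S473 alone is active
#'   towards TSC2/PRAS40 (variants I-III), FALSE for IV and V.
#' @slot mkExtent numeric; extent of Akt inhibition by MK-2206 (0.83).
#' @slot conditions named list of [StressCondition-class] objects.
#' @export
setClass("MTORModel",
  representation(
    variant    = "character",
    species    = "character",
    pools      = "list",
    reactions  = "data.frame",
    parameters = "data.frame",
    sFlag      = "logical",
    mkExtent   = "numeric",
    conditions = "list"
  )
)

setValidity("MTORModel", function(object) {
  msg <- character()
  if (length(object@species) != 25L ||
      !identical(object@species, speciesNames()))
    msg <- c(msg, "species must be the 25 canonical names in canonical order")
  if (anyDuplicated(object@species))
    msg <- c(msg, "species names must be unique")
  pooled <- sort(unlist(object@pools, use.names = FALSE))
  if (!identical(pooled, sort(object@species)))
    msg <- c(msg, "pools must partition the species")
  rt <- object@reactions
  need <- c("substrate", "product", "param", "modifier", "multiplicity",
            "mk_sensitive", "wortmannin_sensitive", "stress_param")
  if (!all(need %in% names(rt))) {
    msg <- c(msg, "reaction table missing columns")
  } else {
    pidx <- .poolIndex()
    if (any(pidx[rt$substrate] != pidx[rt$product]))
      msg <- c(msg, "substrate and product of a reaction must share a pool")
    if (!all(rt$multiplicity %in% c(1L, 2L)))
      msg <- c(msg, "multiplicity must be 1 or 2")
  }
  pt <- object@parameters
  if (!all(c("name", "value", "klass", "lower", "upper", "fixed") %in%
           names(pt))) {
    msg <- c(msg, "parameter table missing columns")
  } else {
    if (anyDuplicated(pt$name)) msg <- c(msg, "parameter names must be unique")
    if (any(pt$value < 0)) msg <- c(msg, "parameter values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' StressCondition: one experimental regime
#'
#' A condition binds the input levels (arsenite stress, insulin, amino acids),
#' inhibitor flags, and a dataset label that keys the condition-specific
#' initial-concentration parameter block.
#'
#' @slot label character; dataset label (e.g. "arsenite").
#' @slot stress logical; arsenite added at t = 0.
#' @slot wortmannin logical; PI3K fully inhibited (Boolean scheme).
#' @slot mk2206 logical; Akt partially inhibited (extent 0.83).
#' @slot insulin numeric; insulin input level (0 under serum starvation).
#' @slot aa numeric; amino-acid input level (1, cells kept in full medium).
#' @slot reference character; label of the condition whose Akt_pT308 initial
#'   anchors this condition's fraction parameter ("" for none). Used for the
#'   wortmannin condition, whose Akt_pT308 initial is expressed as a fraction
#'   of the arsenite-specific initial.
#' @slot normalizeWith character; label of the parent condition whose
#'   simulated time-course means normalize this condition's simulation in the
#'   objective ("" = own condition). Set for artificial no-stress companions.
#' @slot icBlock character; label of the initial-concentration parameter
#'   block this condition reads ("" = own label). No-stress companions borrow
#'   their parent's block instead of adding parameters.
#' @export
setClass("StressCondition",
  representation(label = "character", stress = "logical",
                 wortmannin = "logical", mk2206 = "logical",
                 insulin = "numeric", aa = "numeric",
                 reference = "character", normalizeWith = "character",
                 icBlock = "character"),
  prototype(insulin = 0, aa = 1, reference = "", normalizeWith = "",
            icBlock = "")
)

setValidity("StressCondition", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a non-empty string")
  if (object@insulin < 0 || object@aa < 0)
    msg <- c(msg, "input levels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TimeCourseDataset: tidy phospho time-course records
#'
#' Wraps a data.frame with one row per (condition, readout, time) giving the
#' across-replicate mean relative intensity, its SEM and the replicate count,
#' i.e. the structure of quantified immunoblot time courses.
#'
#' @slot data data.frame with columns condition, readout, time_min, mean,
#'   sem, n_reps.
#' @export
setClass("TimeCourseDataset", representation(data = "data.frame"))

setValidity("TimeCourseDataset", function(object) {
  d <- object@data
  need <- c("condition", "readout", "time_min", "mean", "sem", "n_reps")
  if (!all(need %in% names(d)))
    return(sprintf("data must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(d[c("condition", "readout", "time_min")]))
    msg <- c(msg, "(condition, readout, time) combinations must be unique")
  if (!all(d$readout %in% names(observableDefs())))
    msg <- c(msg, "readout names must be among the nine observables")
  if (any(d$mean < 0)) msg <- c(msg, "mean intensities must be non-negative")
  if (any(d$sem < 0)) msg <- c(msg, "sem must be non-negative")
  if (any(d$n_reps < 1)) msg <- c(msg, "n_reps must be positive")
  if (length(msg)) msg else TRUE
})

#' FitProblem: a weighted least-squares calibration problem
#'
#' Binds a model to one or more datasets, declares which parameters are free,
#' and fixes the numerical policy of the objective.
#'
#' @slot model [MTORModel-class].
#' @slot data [TimeCourseDataset-class]; rows for every fitted condition.
#' @slot freeNames character; names of the free parameters.
#' @slot sigmaFloor numeric; lower bound on the residual sigma (a.u.).
#' @slot normalize character; "mean" (mean-normalize simulated observables per
#'   condition and readout, matching the data processing) or "none".
#' @slot rtol,atol numeric; integrator tolerances used during fitting.
#' @slot cache environment; per-problem precomputations of the objective
#'   (index maps, packed parameter templates). Filled lazily.
#' @export
setClass("FitProblem",
  representation(model = "MTORModel", data = "TimeCourseDataset",
                 freeNames = "character", sigmaFloor = "numeric",
                 normalize = "character", rtol = "numeric", atol = "numeric",
                 cache = "environment")
)

setValidity("FitProblem", function(object) {
  msg <- character()
  pt <- object@model@parameters
  bad <- setdiff(object@freeNames, pt$name)
  if (length(bad))
    msg <- c(msg, sprintf("unknown free parameters: %s",
                          paste(bad, collapse = ", ")))
  labs <- unique(object@data@data$condition)
  known <- names(object@model@conditions)
  if (!all(labs %in% known))
    msg <- c(msg, sprintf("dataset conditions without a condition object: %s",
                          paste(setdiff(labs, known), collapse = ", ")))
  if (object@sigmaFloor <= 0) msg <- c(msg, "sigmaFloor must be positive")
  if (!object@normalize %in% c("mean", "none"))
    msg <- c(msg, "normalize must be 'mean' or 'none'")
  if (length(msg)) msg else TRUE
})

#' MultiStartFit: results of a Latin hypercube multistart optimization
#'
#' @slot results data.frame, one row per start (start index, chi2, convergence
#'   flag, optimizer message, seed), sorted by chi2 (best first).
#' @slot par matrix of log10 parameter vectors, rows aligned with `results`.
#' @slot freeNames character; free parameter names (columns of `par`).
#' @slot seed integer; master seed of the run.
#' @export
setClass("MultiStartFit",
  representation(results = "data.frame", par = "matrix",
                 freeNames = "character", seed = "integer")
)
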