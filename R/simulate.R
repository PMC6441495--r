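#' Assemble the initial state for a condition
#'
#' Reads the condition-specific initial-concentration parameter block.
#' Double-phosphorylated species start at exactly zero (serum-starved
#' baseline), as does IR_beta_pY1146 (no insulin). If the condition carries a
#' reference label, its Akt_pT308 initial is the fraction parameter times the
#' reference condition's Akt_pT308 initial (wortmannin pre-treatment).
#'
#' @param model An [MTORModel-class] object.
#' @param condition A [StressCondition-class]; its label must have a
#'   parameter block in the model.
#' @param params Named parameter vector (natural scale); defaults to the
#'   model's current values.
#' @return Named numeric state vector of length 25 in canonical order.
#' @export
#' @examples
#' m <- buildModel("V")
#' st <- initialState(m, m@conditions$arsenite)
#' st[["Akt_pT308_pS473"]]  # 0
initialState <- function(model, condition, params = parameterValues(model)) {
  stopifnot(is(model, "MTORModel"), is(condition, "StressCondition"))
  lab <- if (nzchar(condition@icBlock)) condition@icBlock else condition@label
  need <- function(nm) {
    if (!nm %in% names(params))
      stop(sprintf("no initial-concentration parameter '%s' for condition '%s'",
                   nm, lab), call. = FALSE)
    params[[nm]]
  }
  st <- stats::setNames(numeric(25), model@species)
  for (sp in setdiff(model@species, .MTOR_ZERO_INITIAL)) {
    if (sp == "Akt_pT308" && nzchar(condition@reference)) {
      st[sp] <- need(sprintf("ic_frac_Akt_pT308.%s", lab)) *
        need(sprintf("ic_Akt_pT308.%s", condition@reference))
    } else {
      st[sp] <- need(sprintf("ic_%s.%s", sp, lab))
    }
  }
  st
}

#' Simulate a model under a condition
#'
#' Integrates the network with a stiff-capable solver (lsoda, compiled
#' right-hand side) from the condition's initial state over the requested
#' time grid. The arsenite stress input is a unit step at t = 0 encoded in
#' the condition, so the system is autonomous.
#'
#' @param model An [MTORModel-class] object.
#' @param condition A [StressCondition-class] object.
#' @param params Named parameter vector (natural scale).
#' @param times Increasing time grid in minutes, starting at 0. The default
#'   mirrors the sampling of the calibration time courses.
#' @param rtol,atol Integrator tolerances.
#' @param engine "C" (compiled, default) or "R" (reference implementation via
#'   [evaluateRHS()]; slow, used for cross-checking).
#' @return Matrix with a `time` column and one column per species; attribute
#'   `condition` carries the condition label. Concentrations in (-1e-8, 0)
#'   are clipped to zero; larger negativity raises an error.
#' @export
#' @examples
#' m <- buildModel("V")
#' p <- groundTruthParams()
#' traj <- simulateModel(m, m@conditions$arsenite, p)
simulateModel <- function(model, condition, params = parameterValues(model),
                          times = defaultTimes(), rtol = 1e-8, atol = 1e-10,
                          engine = c("C", "R")) {
  engine <- match.arg(engine)
  stopifnot(is(model, "MTORModel"), is(condition, "StressCondition"))
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  y0 <- initialState(model, condition, params)
  out <- if (engine == "C") {
    pp <- .packParms(model, params, condition, y0)
    try(deSolve::lsoda(y = unname(y0), times = times, func = "mtor_derivs",
                       parms = pp, dllname = "mtorStress",
                       initfunc = "mtor_init", rtol = rtol, atol = atol),
        silent = TRUE)
  } else {
    mod <- setParameterValues(model, params)
    fr <- function(t, y, p) {
      list(unname(evaluateRHS(mod, y, params, condition, t)))
    }
    try(deSolve::lsoda(y = unname(y0), times = times, func = fr,
                       parms = NULL, rtol = rtol, atol = atol),
        silent = TRUE)
  }
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    cond <- simpleError(sprintf(
      "integration failed for condition '%s' (variant %s)",
      condition@label, model@variant))
    cond$condition_label <- condition@label
    cond$params <- params
    stop(cond)
  }
  states <- out[, -1, drop = FALSE]
  if (any(states < -1e-8))
    stop(sprintf("negative concentrations beyond tolerance (min %.3g) for condition '%s'",
                 min(states), condition@label), call. = FALSE)
  states[states < 0] <- 0
  res <- cbind(time = out[, 1], states)
  colnames(res) <- c("time", model@species)
  attr(res, "condition") <- condition@label
  res
}

#' Default output time grid (minutes)
#'
#' Six sampling times over the first hour of the stress response, dense early
#' where the fast phosphorylation dynamics live.
#' @export
defaultTimes <- function() c(0, 2.5, 5, 15, 30, 60)

#' Map a trajectory to the nine immunoblot observables
#'
#' Each observable is the sum of the concentrations of its summand species
#' ([observableDefs()]).
#'
#' @param model An [MTORModel-class] object.
#' @param traj A trajectory matrix from [simulateModel()].
#' @return data.frame with columns observable, time_min, value (9 rows per
#'   time point).
#' @export
computeObservables <- function(model, traj) {
  om <- .observableMatrix(traj)
  data.frame(
    observable = rep(colnames(om), each = nrow(om)),
    time_min = rep(traj[, "time"], times = ncol(om)),
    value = as.vector(om),
    stringsAsFactors = FALSE)
}

# trajectory -> times x 9 observable matrix
.observableMatrix <- function(traj) {
  defs <- observableDefs()
  om <- vapply(defs, function(sp) {
    if (length(sp) == 1L) traj[, sp] else rowSums(traj[, sp, drop = FALSE])
  }, numeric(nrow(traj)))
  if (is.null(dim(om))) om <- matrix(om, nrow = 1,
                                     dimnames = list(NULL, names(defs)))
  om
}

#' Export a trajectory and its observables as tidy CSV
#'
#' @param model An [MTORModel-class] object.
#' @param traj A trajectory matrix from [simulateModel()].
#' @param path Output CSV path. Columns: condition, series_type
#'   (species/observable), name, time_min, value.
#' @return Invisibly, the exported data.frame.
#' @export
exportTrajectory <- function(model, traj, path) {
  lab <- attr(traj, "condition")
  if (is.null(lab)) lab <- NA_character_
  sp <- data.frame(
    condition = lab, series_type = "species",
    name = rep(model@species, each = nrow(traj)),
    time_min = rep(traj[, "time"], times = length(model@species)),
    value = as.vector(traj[, model@species]),
    stringsAsFactors = FALSE)
  ob <- computeObservables(model, traj)
  ob <- data.frame(condition = lab, series_type = "observable",
                   name = ob$observable, time_min = ob$time_min,
                   value = ob$value, stringsAsFactors = FALSE)
  out <- rbind(sp, ob)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
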