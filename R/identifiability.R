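# A "problem" for the identifiability machinery is either a FitProblem (the
# chi2 objective over its free parameters) or a plain list
#   list(fn = function(named log10 vector) chi2, values = named log10 vector,
#        lower = named, upper = named, freeNames = character)
# used for analytically tractable toy objectives in tests and documentation.

.idFree <- function(problem)
  if (is(problem, "FitProblem")) problem@freeNames else problem$freeNames

.idBounds <- function(problem) {
  if (is(problem, "FitProblem")) .problemBounds(problem)
  else list(lower = problem$lower[.idFree(problem)],
            upper = problem$upper[.idFree(problem)])
}

.idObjective <- function(problem) {
  if (is(problem, "FitProblem")) {
    function(logp) as.numeric(chi2Objective(problem, logp))
  } else {
    fixed <- problem$values
    free <- problem$freeNames
    function(logp) {
      full <- fixed
      full[free] <- logp
      as.numeric(problem$fn(full))
    }
  }
}

.idFix <- function(problem, name, log10value) {
  if (is(problem, "FitProblem")) {
    v <- stats::setNames(10^log10value, name)
    problem@model <- setParameterValues(problem@model, v)
    problem@freeNames <- setdiff(problem@freeNames, name)
  } else {
    problem$values[name] <- log10value
    problem$freeNames <- setdiff(problem$freeNames, name)
  }
  problem
}

#' Profile likelihood of one parameter
#'
#' Steps the parameter away from its optimum in both directions,
#' re-optimizing all other free parameters at every grid point. A direction
#' terminates when the re-optimized chi-squared exceeds the best value by
#' `deltaChi2` (identifiable on that side) or the parameter bound is reached
#' (non-identifiable). Step sizes adapt to target chi-squared increments of
#' about one tenth of `deltaChi2`. Re-optimization failures flag the point
#' and the profile continues.
#'
#' @param problem A [FitProblem-class], or a toy problem list (see the
#'   package source of this file) with elements `fn`, `values`, `lower`,
#'   `upper`, `freeNames`.
#' @param best Named log10 parameter vector at the optimum (e.g.
#'   `bestFit(fit)$logp`), covering the free parameters.
#' @param parameter Name of the profiled parameter.
#' @param deltaChi2 Threshold above the minimum (default 3.84, the 95
#'   percent pointwise cutoff for one degree of freedom).
#' @param maxSteps Cap on grid points per direction (default 50).
#' @param reoptMaxit Iteration cap of each re-optimization.
#' @return List of class `likelihoodProfile`: `parameter`, `grid`
#'   (data.frame value/chi2/flagged, ascending in value), `chi2_best`,
#'   `status` in identifiable / non_identifiable_lower /
#'   non_identifiable_upper / non_identifiable_both.
#' @export
profileLikelihood <- function(problem, best, parameter, deltaChi2 = 3.84,
                              maxSteps = 50, reoptMaxit = 60) {
  free <- .idFree(problem)
  stopifnot(parameter %in% free)
  b <- .idBounds(problem)
  obj <- .idObjective(problem)
  best <- best[free]
  chi2_0 <- obj(best)
  others <- setdiff(free, parameter)
  profilePoint <- function(pval, warm) {
    # chi2 minimized over the other free parameters at fixed `parameter`
    if (!length(others))
      return(list(chi2 = obj(stats::setNames(pval, parameter)), warm = warm,
                  flagged = FALSE))
    f <- function(lo) {
      full <- best
      full[others] <- lo
      full[parameter] <- pval
      obj(full)
    }
    fit <- tryCatch(
      stats::optim(warm, f, method = "L-BFGS-B", lower = b$lower[others],
                   upper = b$upper[others],
                   control = list(maxit = reoptMaxit)),
      error = function(e) NULL)
    if (is.null(fit)) list(chi2 = NA_real_, warm = warm, flagged = TRUE)
    else list(chi2 = fit$value, warm = fit$par, flagged = FALSE)
  }
  target <- 0.1 * deltaChi2
  runDirection <- function(dir) {
    lo <- b$lower[[parameter]]; hi <- b$upper[[parameter]]
    step <- max((hi - lo) / 25, 1e-3)
    p <- best[[parameter]]
    warm <- best[others]
    chi2_prev <- chi2_0
    pts <- list()
    hit_bound <- FALSE
    for (i in seq_len(maxSteps)) {
      pnew <- p + dir * step
      at_bound <- FALSE
      if (pnew <= lo) { pnew <- lo; at_bound <- TRUE }
      if (pnew >= hi) { pnew <- hi; at_bound <- TRUE }
      res <- profilePoint(pnew, warm)
      warm <- res$warm
      pts[[i]] <- data.frame(value = pnew, chi2 = res$chi2,
                             flagged = res$flagged)
      if (!res$flagged) {
        inc <- res$chi2 - chi2_prev
        chi2_prev <- res$chi2
        if (res$chi2 > chi2_0 + deltaChi2)
          return(list(points = pts, identifiable = TRUE))
        if (inc < 0.2 * target) step <- min(step * 1.8, (hi - lo) / 4)
        else if (inc > 5 * target) step <- max(step * 0.5, 1e-4)
      }
      if (at_bound) { hit_bound <- TRUE; break }
      p <- pnew
    }
    list(points = pts, identifiable = FALSE)
  }
  up <- runDirection(+1)
  down <- runDirection(-1)
  grid <- rbind(do.call(rbind, rev(down$points)),
                data.frame(value = best[[parameter]], chi2 = chi2_0,
                           flagged = FALSE),
                do.call(rbind, up$points))
  grid <- grid[order(grid$value), ]
  rownames(grid) <- NULL
  status <- if (down$identifiable && up$identifiable) "identifiable"
    else if (down$identifiable) "non_identifiable_upper"
    else if (up$identifiable) "non_identifiable_lower"
    else "non_identifiable_both"
  structure(list(parameter = parameter, grid = grid, chi2_best = chi2_0,
                 status = status), class = "likelihoodProfile")
}

#' @export
print.likelihoodProfile <- function(x, ...) {
  cat(sprintf("Likelihood profile of %s: %s (%d grid points, chi2 min %.4g)\n",
              x$parameter, x$status, nrow(x$grid), x$chi2_best))
  invisible(x)
}

#' Keep the better of two chi-squared clusters
#'
#' One-dimensional two-cluster partition (k-means with deterministic
#' extreme-value initial centers) of the chi-squared values of a multistart
#' run; members of the cluster with the lower mean are retained. With fewer
#' than two distinct values the clustering is degenerate and everything is
#' returned.
#'
#' @param fits A [MultiStartFit-class] object, or a numeric chi-squared
#'   vector.
#' @return Same type as the input, restricted to the retained fits.
#' @export
filterFitsByCluster <- function(fits) {
  chi2 <- if (is(fits, "MultiStartFit")) fits@results$chi2 else fits
  stopifnot(length(chi2) >= 2)
  keep <- if (length(unique(chi2)) < 2) {
    rep(TRUE, length(chi2))
  } else {
    km <- stats::kmeans(matrix(chi2, ncol = 1),
                        centers = matrix(range(chi2), ncol = 1))
    better <- which.min(km$centers)
    km$cluster == better
  }
  if (is(fits, "MultiStartFit")) {
    fits@results <- fits@results[keep, , drop = FALSE]
    fits@par <- fits@par[keep, , drop = FALSE]
    fits
  } else chi2[keep]
}

#' Mode of a kernel-smoothed parameter distribution
#'
#' Argmax of a Gaussian kernel density (bandwidth by the normal reference
#' rule) over log10 parameter samples. Deterministic. With a multimodal
#' sample one of the modes is returned; gate on [isUnimodal()] first.
#'
#' @param samples Numeric vector of at least 5 log10 parameter values.
#' @return The density mode (lies within the sample range).
#' @export
kdeMode <- function(samples) {
  if (length(samples) < 5)
    stop("at least 5 samples are required", call. = FALSE)
  if (diff(range(samples)) < 1e-12) return(samples[1])
  d <- stats::density(samples)
  d$x[which.max(d$y)]
}

#' Unimodality heuristic for multistart parameter samples
#'
#' TRUE iff at least 80 percent of the samples lie within 0.5 log10 units of
#' the kernel density mode — i.e. the fits end nearly always in the same
#' value range regardless of the starting point. The boundary (exactly 0.8)
#' is inclusive.
#'
#' @param samples Numeric vector of at least 5 log10 parameter values.
#' @export
isUnimodal <- function(samples) {
  if (length(samples) < 5)
    stop("at least 5 samples are required", call. = FALSE)
  m <- kdeMode(samples)
  mean(abs(samples - m) <= 0.5) >= 0.8
}

#' Iterative identifiability-driven parameter fixing
#'
#' The calibration loop: multistart fit, profile-likelihood classification of
#' every free parameter, fixing of the identifiable ones at their optima; if
#' an iteration identifies none, the multistart solutions are filtered to
#' the better chi-squared cluster and every parameter with a unimodal sample
#' distribution is fixed at its kernel density mode. Iterations repeat until
#' no free parameters remain, `maxIterations` is reached, or an iteration
#' can fix nothing ("stalled" — a legitimate terminal state).
#'
#' @param problem A [FitProblem-class] (or toy problem list, see
#'   [profileLikelihood()]).
#' @param nStarts Starts per multistart run.
#' @param seed Master seed; iteration i uses seed + i.
#' @param maxIterations Iteration cap (default 20).
#' @param deltaChi2,maxSteps Passed to [profileLikelihood()].
#' @return List: `logp` (named log10 vector of every originally free
#'   parameter), `ledger` (data.frame iteration / parameter / log10_value /
#'   method / evidence), `status` ("complete", "stalled" or
#'   "max_iterations"), `best_chi2`.
#' @export
iterativeFixing <- function(problem, nStarts = 25, seed = 1,
                            maxIterations = 20, deltaChi2 = 3.84,
                            maxSteps = 50) {
  original <- .idFree(problem)
  ledger <- list()
  status <- "max_iterations"
  final <- stats::setNames(rep(NA_real_, length(original)), original)
  best_chi2 <- NA_real_
  for (iter in seq_len(maxIterations)) {
    free <- .idFree(problem)
    if (!length(free)) { status <- "complete"; break }
    fit <- .idMultistart(problem, nStarts, (seed + iter) %%
                           .Machine$integer.max)
    best <- fit$logp
    best_chi2 <- fit$chi2
    fixed_now <- character()
    for (p in free) {
      prof <- profileLikelihood(problem, best, p, deltaChi2 = deltaChi2,
                                maxSteps = maxSteps)
      if (prof$status == "identifiable") {
        problem <- .idFix(problem, p, best[[p]])
        final[p] <- best[[p]]
        ledger[[length(ledger) + 1L]] <- data.frame(
          iteration = iter, parameter = p, log10_value = best[[p]],
          method = "ple", evidence = "profile exceeds threshold both sides")
        fixed_now <- c(fixed_now, p)
      }
    }
    if (!length(fixed_now)) {
      keep <- filterFitsByCluster(fit$all_chi2)
      keep_idx <- fit$all_chi2 %in% keep
      for (p in .idFree(problem)) {
        samples <- fit$all_par[keep_idx, p]
        if (length(samples) >= 5 && isUnimodal(samples)) {
          v <- kdeMode(samples)
          problem <- .idFix(problem, p, v)
          final[p] <- v
          ledger[[length(ledger) + 1L]] <- data.frame(
            iteration = iter, parameter = p, log10_value = v,
            method = "kde_mode",
            evidence = sprintf("unimodal over %d retained fits",
                               length(samples)))
          fixed_now <- c(fixed_now, p)
        }
      }
    }
    if (!length(fixed_now)) { status <- "stalled"; break }
    if (!length(.idFree(problem))) { status <- "complete"; break }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger)
    else data.frame(iteration = integer(), parameter = character(),
                    log10_value = numeric(), method = character(),
                    evidence = character())
  list(logp = final, ledger = ledger, status = status,
       best_chi2 = best_chi2)
}

# multistart over either problem representation; returns best vector plus
# the full solution set for cluster filtering
.idMultistart <- function(problem, nStarts, seed) {
  free <- .idFree(problem)
  if (is(problem, "FitProblem")) {
    fit <- fitMultistart(problem, nStarts = nStarts, seed = seed)
    best <- bestFit(fit)
    list(logp = best$logp, chi2 = best$chi2,
         all_chi2 = fit@results$chi2, all_par = fit@par)
  } else {
    b <- .idBounds(problem)
    obj <- .idObjective(problem)
    starts <- lhsStarts(list(lower = b$lower, upper = b$upper), nStarts,
                        seed)
    pars <- matrix(NA_real_, nStarts, length(free),
                   dimnames = list(NULL, free))
    chi2 <- numeric(nStarts)
    for (i in seq_len(nStarts)) {
      fit <- tryCatch(
        stats::optim(starts[i, ], function(lp) obj(stats::setNames(lp, free)),
                     method = "L-BFGS-B", lower = b$lower, upper = b$upper),
        error = function(e) NULL)
      if (is.null(fit)) { chi2[i] <- 1e12; pars[i, ] <- starts[i, ] }
      else { chi2[i] <- fit$value; pars[i, ] <- fit$par }
    }
    ord <- order(chi2)
    list(logp = stats::setNames(pars[ord[1], ], free), chi2 = chi2[ord[1]],
         all_chi2 = chi2[ord], all_par = pars[ord, , drop = FALSE])
  }
}

#' Replay a fixing ledger
#'
#' Applies the ledger's fixes in order to a fresh problem and returns the
#' final log10 vector — bitwise identical to the vector the original run
#' produced.
#'
#' @param ledger data.frame from [iterativeFixing()].
#' @return Named log10 vector in ledger order.
#' @export
replayFixingLedger <- function(ledger) {
  stats::setNames(ledger$log10_value, ledger$parameter)
}
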