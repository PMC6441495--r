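#' Define a calibration problem
#'
#' Binds a model to a dataset, declares the free parameters and fixes the
#' objective's numerical policy. Conditions appearing in the data but missing
#' from the model are added automatically when they are no-stress companions
#' of a known condition.
#'
#' @param model An [MTORModel-class] object.
#' @param data A [TimeCourseDataset-class] (bind several with
#'   [bindDatasets()]).
#' @param freeNames Free parameter names; default all non-fixed parameters.
#' @param sigmaFloor Lower bound (a.u.) on the residual sigma, guarding
#'   against zero-SEM points. Default 0.05.
#' @param normalize "mean" (default): mean-normalize simulated observables
#'   per (condition, readout) over the fitted time points, mirroring the
#'   per-replicate normalization of the data; no-stress companions are
#'   normalized with their parent condition's factors. "none": compare raw
#'   concentrations.
#' @param rtol,atol Integrator tolerances used inside the objective (looser
#'   than simulation defaults; the objective is evaluated thousands of
#'   times).
#' @return A [FitProblem-class] object.
#' @export
fitProblem <- function(model, data, freeNames = freeParameterNames(model),
                       sigmaFloor = 0.05, normalize = c("mean", "none"),
                       rtol = 1e-6, atol = 1e-8) {
  normalize <- match.arg(normalize)
  labs <- unique(tcData(data)$condition)
  for (lab in setdiff(labs, names(model@conditions))) {
    parent <- sub("_no_stress$", "", lab)
    if (parent != lab && parent %in% names(model@conditions)) {
      model@conditions[[lab]] <-
        noStressCompanion(model@conditions[[parent]])
    }
  }
  new("FitProblem", model = model, data = data, freeNames = freeNames,
      sigmaFloor = sigmaFloor, normalize = normalize, rtol = rtol,
      atol = atol, cache = new.env(parent = emptyenv()))
}

# Precompute everything the objective needs that does not depend on the
# parameter values: per-condition data/time index maps, initial-state and
# rate-constant index vectors into the full parameter vector, packed
# parameter templates for the compiled right-hand side, and the observable
# summand matrix.  The objective then reduces to indexed vector arithmetic
# around the lsoda call.
.compileObjective <- function(problem) {
  model <- problem@model
  pt <- model@parameters
  pnames <- pt$name
  d <- tcData(problem@data)
  obs_names <- names(observableDefs())
  sp <- model@species
  OB <- vapply(observableDefs(), function(s) as.numeric(sp %in% s),
               numeric(25))
  pidx <- .poolIndex()
  poolM <- t(vapply(seq_along(model@pools), function(i) as.numeric(pidx == i),
                    numeric(25)))
  rt <- model@reactions
  nr <- nrow(rt)
  sp_i <- stats::setNames(seq_along(sp), sp)
  c1_idx <- match("k_stress_mTORC1", pnames)    # NA if variant lacks it
  conds <- list()
  for (lab in unique(d$condition)) {
    cond <- model@conditions[[lab]]
    g <- d[d$condition == lab, ]
    times_d <- sort(unique(g$time_min))
    grid <- sort(unique(c(0, times_d)))
    if (length(grid) < 2) grid <- c(grid, grid + 1e-3)  # solver needs 2
    icb <- if (nzchar(cond@icBlock)) cond@icBlock else lab
    ic_idx <- integer(25); frac_i <- 0L; ref_i <- 0L; akt_pos <- 0L
    for (j in seq_along(sp)) {
      s <- sp[j]
      if (s %in% .MTOR_ZERO_INITIAL) next
      if (s == "Akt_pT308" && nzchar(cond@reference)) {
        frac_i <- match(sprintf("ic_frac_Akt_pT308.%s", icb), pnames)
        ref_i <- match(sprintf("ic_Akt_pT308.%s", cond@reference), pnames)
        akt_pos <- j
        if (is.na(frac_i) || is.na(ref_i))
          stop("missing initial-concentration parameters for condition ",
               lab, call. = FALSE)
      } else {
        k <- match(sprintf("ic_%s.%s", s, icb), pnames)
        if (is.na(k))
          stop(sprintf("no initial-concentration parameter for %s in '%s'",
                       s, icb), call. = FALSE)
        ic_idx[j] <- k
      }
    }
    u_stress <- as.numeric(cond@stress)
    mkfac <- rep(1, nr)
    if (cond@mk2206) mkfac[rt$mk_sensitive] <- 1 - model@mkExtent
    kidx <- match(rt$param, pnames)
    sidx <- match(rt$stress_param, pnames)
    sidx[is.na(sidx)] <- 0L
    wmask <- if (cond@wortmannin) rt$wortmannin_sensitive
             else rep(FALSE, nr)
    tmpl <- numeric(.NPARMS)
    tmpl[1] <- nr
    tmpl[2] <- if (model@sFlag) 1 else 0
    tmpl[13] <- cond@insulin
    base <- 13 + 5 * (seq_len(nr) - 1)
    tmpl[base + 1] <- sp_i[rt$substrate] - 1
    tmpl[base + 2] <- sp_i[rt$product] - 1
    tmpl[base + 4] <- .MODIFIER_CODES[rt$modifier]
    conds[[lab]] <- list(
      label = lab, grid = grid,
      parent = if (nzchar(cond@normalizeWith)) cond@normalizeWith else lab,
      row_t = match(g$time_min, grid), row_o = match(g$readout, obs_names),
      mean = g$mean, sigma = pmax(g$sem, problem@sigmaFloor),
      data_rows = match(times_d, grid),
      ic_idx = ic_idx, frac_i = frac_i, ref_i = ref_i, akt_pos = akt_pos,
      kmul = rt$multiplicity * mkfac, kidx = kidx, sidx = sidx,
      u_stress = u_stress, wmask = wmask,
      aa = cond@aa, tmpl = tmpl, kslot = base + 3, sslot = base + 5)
  }
  list(pnames = pnames, pvalues = stats::setNames(pt$value, pnames),
       free_idx = match(problem@freeNames, pnames),
       kaa_idx = match("k_aa", pnames), c1_idx = c1_idx,
       OB = OB, poolM = poolM, conds = conds,
       obs_names = obs_names)
}

.objectiveContext <- function(problem) {
  if (is.null(problem@cache$ctx))
    problem@cache$ctx <- .compileObjective(problem)
  problem@cache$ctx
}

#' Weighted least-squares objective
#'
#' chi^2 = sum over fitted data points of
#' `((sim - mean) / max(sem, sigmaFloor))^2`, with the simulated observables
#' optionally mean-normalized per (condition, readout) to match the data
#' processing. Each condition is simulated once per evaluation;
#' deterministic. An integration failure returns the penalty value 1e12
#' (attribute `failed` set), so multistart optimization continues.
#'
#' @param problem A [FitProblem-class] object.
#' @param logp Numeric vector of log10 values of the free parameters, in
#'   `problem@freeNames` order.
#' @return Non-negative chi-squared value.
#' @export
chi2Objective <- function(problem, logp) {
  stopifnot(length(logp) == length(problem@freeNames))
  ctx <- .objectiveContext(problem)
  params <- ctx$pvalues
  params[ctx$free_idx] <- 10^as.numeric(logp)
  oms <- list()
  for (cc in ctx$conds) {
    y0 <- numeric(25)
    nz <- which(cc$ic_idx > 0L)
    y0[nz] <- params[cc$ic_idx[nz]]
    if (cc$akt_pos > 0L)
      y0[cc$akt_pos] <- params[cc$frac_i] * params[cc$ref_i]
    C <- as.numeric(ctx$poolM %*% y0)
    keff <- params[cc$kidx] * cc$kmul
    kstr <- c(0, params)[cc$sidx + 1L] * cc$u_stress
    if (any(cc$wmask)) { keff[cc$wmask] <- 0; kstr[cc$wmask] <- 0 }
    pp <- cc$tmpl
    pp[3:11] <- C
    pp[12] <- params[ctx$kaa_idx] * cc$aa +
      (if (!is.na(ctx$c1_idx)) params[ctx$c1_idx] * cc$u_stress else 0)
    pp[cc$kslot] <- keff
    pp[cc$sslot] <- kstr
    out <- try(suppressWarnings(
      deSolve::lsoda(y = y0, times = cc$grid, func = "mtor_derivs",
                     parms = pp, dllname = "mtorStress",
                     initfunc = "mtor_init", rtol = problem@rtol,
                     atol = problem@atol)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(cc$grid) ||
        anyNA(out)) {
      res <- 1e12
      attr(res, "failed") <- cc$label
      return(res)
    }
    st <- out[, -1, drop = FALSE]
    st[st < 0] <- 0
    oms[[cc$label]] <- st %*% ctx$OB
  }
  # normalization factors from each parent condition's own data time points
  factors <- list()
  if (problem@normalize == "mean") {
    for (cc in ctx$conds) {
      parent <- cc$parent
      if (!is.null(factors[[parent]])) next
      src <- if (!is.null(ctx$conds[[parent]])) ctx$conds[[parent]] else cc
      f <- colMeans(oms[[src$label]][src$data_rows, , drop = FALSE])
      f[f <= 1e-8] <- 1
      factors[[parent]] <- f
    }
  } else {
    ones <- rep(1, length(ctx$obs_names))
    for (cc in ctx$conds) factors[[cc$parent]] <- ones
  }
  chi2 <- 0
  for (cc in ctx$conds) {
    f <- factors[[cc$parent]]
    sim <- oms[[cc$label]][cbind(cc$row_t, cc$row_o)] / f[cc$row_o]
    chi2 <- chi2 + sum(((sim - cc$mean) / cc$sigma)^2)
  }
  chi2
}

#' Latin hypercube starting points
#'
#' Stratified sampling of `n` starting points in log10 parameter space: each
#' free parameter's `n` draws occupy `n` equal-width bins of its range
#' exactly once. Parameters with degenerate bounds (lower = upper) are held
#' at that value and excluded from stratification. Reproducible given the
#' seed.
#'
#' @param problem A [FitProblem-class], or a list with numeric `lower` and
#'   `upper` (log10 bounds, equal length).
#' @param n Number of starts.
#' @param seed Integer seed.
#' @return n x k matrix of log10 parameter vectors (columns named when
#'   bounds are).
#' @export
lhsStarts <- function(problem, n, seed = 1) {
  stopifnot(n >= 1)
  b <- if (is(problem, "FitProblem")) .problemBounds(problem) else problem
  lower <- b$lower; upper <- b$upper
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  k <- length(lower)
  active <- which(upper > lower)
  out <- matrix(rep(lower, each = n), nrow = n,
                dimnames = list(NULL, names(lower)))
  if (length(active)) {
    u <- .withSeed(seed, lhs::randomLHS(n, length(active)))
    out[, active] <- sweep(sweep(u, 2, (upper - lower)[active], "*"),
                           2, lower[active], "+")
  }
  out
}

.problemBounds <- function(problem) {
  pt <- problem@model@parameters
  i <- match(problem@freeNames, pt$name)
  list(lower = stats::setNames(pt$lower[i], pt$name[i]),
       upper = stats::setNames(pt$upper[i], pt$name[i]))
}

#' Multistart local optimization
#'
#' Runs a bound-constrained quasi-Newton local fit (L-BFGS-B in log10
#' parameter space, finite-difference gradients) from each Latin hypercube
#' starting point. All starts are retained — failed starts are flagged, not
#' dropped — and results are sorted by chi-squared, best first.
#'
#' @param problem A [FitProblem-class] object.
#' @param nStarts Number of Latin hypercube starts.
#' @param seed Integer seed (start generation only; the objective is
#'   deterministic).
#' @param starts Optional matrix of log10 starting points overriding the
#'   Latin hypercube draw.
#' @param maxit Iteration cap per start.
#' @return A [MultiStartFit-class] object.
#' @export
fitMultistart <- function(problem, nStarts = 25, seed = 1, starts = NULL,
                          maxit = 150) {
  stopifnot(nStarts >= 1)
  b <- .problemBounds(problem)
  if (is.null(starts)) starts <- lhsStarts(problem, nStarts, seed)
  stopifnot(ncol(starts) == length(problem@freeNames))
  obj <- function(lp) as.numeric(chi2Objective(problem, lp))
  rows <- vector("list", nrow(starts))
  pars <- matrix(NA_real_, nrow(starts), length(problem@freeNames),
                 dimnames = list(NULL, problem@freeNames))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(start_index = i, chi2 = 1e12,
                              converged = FALSE, message = "optim error",
                              seed = seed)
      pars[i, ] <- starts[i, ]
    } else {
      rows[[i]] <- data.frame(start_index = i, chi2 = fit$value,
                              converged = fit$convergence == 0 &&
                                fit$value < 1e12,
                              message = if (is.null(fit$message)) ""
                                        else fit$message,
                              seed = seed)
      pars[i, ] <- fit$par
    }
  }
  res <- do.call(rbind, rows)
  ord <- order(res$chi2)
  new("MultiStartFit", results = res[ord, , drop = FALSE],
      par = pars[ord, , drop = FALSE], freeNames = problem@freeNames,
      seed = as.integer(seed))
}

#' @describeIn fitMultistart Fit report: one row per start, sorted by chi2.
#' @param fit A [MultiStartFit-class] object.
#' @export
fitResults <- function(fit) fit@results

#' @describeIn fitMultistart Best chi2 and log10 parameter vector.
#' @export
bestFit <- function(fit) {
  list(chi2 = fit@results$chi2[1],
       logp = stats::setNames(fit@par[1, ], fit@freeNames),
       converged = fit@results$converged[1])
}

#' @export
setMethod("show", "MultiStartFit", function(object) {
  r <- object@results
  cat(sprintf("MultiStartFit: %d starts (%d converged), seed %d\n",
              nrow(r), sum(r$converged), object@seed))
  cat(sprintf("  best chi2 %.6g; %d free parameter(s)\n",
              r$chi2[1], length(object@freeNames)))
})

#' Export a fit report as CSV
#' @param fit A [MultiStartFit-class] object.
#' @param path Output path. One row per start: seed, start index, chi2,
#'   convergence flag and the log10 parameter values.
#' @export
writeFitReport <- function(fit, path) {
  out <- cbind(fit@results[c("seed", "start_index", "chi2", "converged")],
               as.data.frame(fit@par))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Extent of inhibition from paired time courses
#'
#' Quantifies how strongly an inhibitor suppresses the stress induction of a
#' readout. If the treated time course shows no significant change across
#' time points (one-way ANOVA on the replicate summary statistics, `alpha` =
#' 0.05), inhibition is complete and 1.0 is returned (the Boolean case).
#' Otherwise the ordinary least-squares slopes of mean intensity versus time
#' are compared: `extent = clip(1 - slope_treated / slope_control, 0, 1)`
#' (partial inhibition).
#'
#' @param control,treated [TimeCourseDataset-class] objects covering the
#'   readout over a shared induction window.
#' @param readout One of the nine observable names.
#' @param alpha Significance level of the induction test.
#' @return Fraction in \[0, 1\].
#' @export
extentOfInhibition <- function(control, treated, readout, alpha = 0.05) {
  pull <- function(ds) {
    d <- tcData(ds)
    d <- d[d$readout == readout, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("readout '%s' absent", readout), call. = FALSE)
    d[order(d$time_min), ]
  }
  dc <- pull(control); dt <- pull(treated)
  p <- .anovaFromSummary(dt)
  if (!is.na(p) && p >= alpha) return(1.0)
  slope <- function(d) unname(stats::coef(stats::lm(mean ~ time_min, d))[2])
  bC <- slope(dc)
  if (bC <= 0)
    stop("control time course shows no positive induction slope",
         call. = FALSE)
  min(max(1 - slope(dt) / bC, 0), 1)
}

# one-way ANOVA across time points from per-group mean/sem/n; NA when the
# within-group variance is not estimable (single replicates or zero sem)
.anovaFromSummary <- function(d) {
  n <- d$n_reps; m <- d$mean; s <- d$sem * sqrt(d$n_reps)
  k <- nrow(d); N <- sum(n)
  if (k < 2 || N <= k || all(s == 0)) return(NA_real_)
  grand <- sum(n * m) / N
  msb <- sum(n * (m - grand)^2) / (k - 1)
  msw <- sum((n - 1) * s^2) / (N - k)
  if (msw <= 0) return(NA_real_)
  stats::pf(msb / msw, k - 1, N - k, lower.tail = FALSE)
}
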