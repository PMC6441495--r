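# Shared fixtures, built once per test run.

.fx <- new.env()

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

gtModelV <- function() fx("m5", function() {
  setParameterValues(buildModel("V"), groundTruthParams("V"))
})

gtModelIII <- function() fx("m3", function() {
  setParameterValues(buildModel("III"), groundTruthParams("III"))
})

gtModelII <- function() fx("m2", function() {
  setParameterValues(buildModel("II"), groundTruthParams("II"))
})

# noise-free three-condition study from the model V truth (normalized)
noiseFreeStudy <- function() fx("nf", function() {
  m <- gtModelV()
  generateDataset(m, groundTruthParams("V"), m@conditions, nReps = 1, cv = 0)
})

# unnormalized noise-free study (raw concentrations)
rawStudy <- function() fx("raw", function() {
  m <- gtModelV()
  generateDataset(m, groundTruthParams("V"), m@conditions, nReps = 1,
                  cv = 0, normalize = FALSE)
})

# random admissible state: non-negative, pools on the usual scale
randomState <- function() {
  x <- stats::runif(25, 0, 1)
  names(x) <- speciesNames()
  x
}

# random parameter vector within bounds for a model
randomParams <- function(model) {
  pt <- parameterTable(model)
  lp <- stats::runif(nrow(pt), pt$lower, pt$upper)
  stats::setNames(10^lp, pt$name)
}

# separable quadratic toy problem for the identifiability machinery:
# chi2(x) = sum_i w_i * (x_i - centre_i)^2
quadraticToy <- function(centre, weights, lower = rep(-5, length(centre)),
                         upper = rep(3, length(centre))) {
  nm <- names(centre)
  list(
    fn = function(logp) sum(weights * (logp[nm] - centre)^2),
    values = centre,
    lower = stats::setNames(lower, nm),
    upper = stats::setNames(upper, nm),
    freeNames = nm)
}
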