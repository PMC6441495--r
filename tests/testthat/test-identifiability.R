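test_that("profiles of a convex objective match the analytic conditional minimum", {
  toy <- quadraticToy(centre = c(a = -1, b = 0.5), weights = c(40, 40))
  prof <- profileLikelihood(toy, best = c(a = -1, b = 0.5), parameter = "a")
  expect_s3_class(prof, "likelihoodProfile")
  expect_identical(prof$status, "identifiable")
  # separable quadratic: the profile is the marginal parabola 40 (a + 1)^2
  ok <- !prof$grid$flagged
  expect_equal(prof$grid$chi2[ok], 40 * (prof$grid$value[ok] + 1)^2,
               tolerance = 1e-4)
  # lower envelope: no grid point undercuts the optimum
  expect_gte(min(prof$grid$chi2[ok]), -1e-8)
  expect_equal(prof$grid$chi2[which.min(abs(prof$grid$value + 1))], 0,
               tolerance = 1e-8)
})

test_that("a perfectly redundant pair profiles flat to both bounds", {
  # only the sum a + b is determined, and the partner can compensate over
  # the whole box: both parameters non-identifiable
  ridge <- list(
    fn = function(logp) 50 * (logp[["a"]] + logp[["b"]])^2,
    values = c(a = 0.5, b = -0.5),
    lower = c(a = -3, b = -3), upper = c(a = 3, b = 3),
    freeNames = c("a", "b"))
  for (pn in c("a", "b")) {
    prof <- profileLikelihood(ridge, best = c(a = 0.5, b = -0.5),
                              parameter = pn)
    expect_identical(prof$status, "non_identifiable_both")
    expect_lt(max(prof$grid$chi2[!prof$grid$flagged]), 3.84)
  }
})

test_that("stress-input strengths are identifiable on the pinned synthetic study", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  ds <- generateDataset(m, p, m@conditions$arsenite, nReps = 1, cv = 0)
  free <- c("k_stress_PI3K", "k_stress_Akt_S473")
  prob <- fitProblem(m, ds, freeNames = free)
  # the Akt-S473 input strength lies in the interior of its range and
  # profiles as identifiable
  prof <- profileLikelihood(prob, best = log10(p[free]),
                            parameter = "k_stress_Akt_S473", maxSteps = 25)
  expect_identical(prof$status, "identifiable")
  # the PI3K input strength sits at its biological cap (1e-2 per min, the
  # slow-activation bound): the profile pins it from below and terminates
  # at the cap from above
  prof2 <- profileLikelihood(prob, best = log10(p[free]),
                             parameter = "k_stress_PI3K", maxSteps = 25)
  expect_identical(prof2$status, "non_identifiable_upper")
  lower_side <- prof2$grid[prof2$grid$value < log10(p[["k_stress_PI3K"]]), ]
  expect_gt(max(lower_side$chi2, na.rm = TRUE), prof2$chi2_best + 3.84)
})

test_that("cluster filtering keeps the better chi-squared population", {
  expect_setequal(filterFitsByCluster(c(1, 1.1, 0.9, 100, 110)),
                  c(1, 1.1, 0.9))
  expect_identical(filterFitsByCluster(rep(3, 6)), rep(3, 6))
  set.seed(5)
  for (rep in 1:5) {
    x <- stats::runif(20, 0, 100)
    keep <- filterFitsByCluster(x)
    expect_gt(length(keep), 0)
    expect_true(all(keep %in% x))
    expect_lt(mean(keep), mean(setdiff(x, keep)))
  }
  expect_error(filterFitsByCluster(1), "length")
})

test_that("the kernel density mode locates tight clusters", {
  set.seed(9)
  x <- -2 + stats::rnorm(50, 0, 1e-3)
  expect_lt(abs(kdeMode(x) + 2), 1e-2)
  expect_gte(kdeMode(x), min(x) - 1e-6)
  expect_lte(kdeMode(x), max(x) + 1e-6)
  # bimodal: one of the two modes, caller gates on unimodality
  y <- c(stats::rnorm(40, -4, 0.05), stats::rnorm(40, 0, 0.05))
  expect_true(min(abs(kdeMode(y) - c(-4, 0))) < 0.1)
  expect_error(kdeMode(1:3), "at least 5")
})

test_that("the unimodality rule follows the 80 percent window heuristic", {
  expect_true(isUnimodal(c(-2, -2.05, -1.95, -2.01, -1.99)))
  expect_false(isUnimodal(c(rep(-4, 5), rep(0, 5))))
  # exactly 80 percent inside the half-log window: boundary inclusive
  x <- c(rep(0, 8), 3, 3)
  expect_equal(mean(abs(x - kdeMode(x)) <= 0.5), 0.8)
  expect_true(isUnimodal(x))
  expect_error(isUnimodal(1:4), "at least 5")
})

test_that("a fully identifiable toy is fixed by profiles in one iteration", {
  toy <- quadraticToy(centre = c(a = -1, b = 0.5, c = 2),
                      weights = c(30, 30, 30))
  out <- iterativeFixing(toy, nStarts = 8, seed = 2, maxIterations = 3)
  expect_identical(out$status, "complete")
  expect_identical(sort(out$ledger$parameter), c("a", "b", "c"))
  expect_identical(unique(out$ledger$method), "ple")
  expect_identical(unique(out$ledger$iteration), 1L)
  expect_equal(unname(out$logp[c("a", "b", "c")]), c(-1, 0.5, 2),
               tolerance = 1e-3)
  # replaying the ledger reproduces the final vector bitwise
  rep <- replayFixingLedger(out$ledger)
  expect_identical(rep[names(out$logp)], out$logp)
})

test_that("weakly determined parameters fall to the density-mode route", {
  # b moves the objective too little to cross the profile threshold
  # anywhere in its range, but multistart solutions still settle near its
  # optimum -> fixed at the kernel density mode
  toy <- quadraticToy(centre = c(a = -1, b = 0.5), weights = c(50, 0.05))
  out <- iterativeFixing(toy, nStarts = 12, seed = 3, maxIterations = 5)
  led <- out$ledger
  expect_identical(led$method[led$parameter == "a"], "ple")
  expect_identical(led$method[led$parameter == "b"], "kde_mode")
  expect_identical(out$status, "complete")
  expect_lt(abs(out$logp[["a"]] + 1), 1e-2)
})

test_that("an unresolvable redundancy terminates as stalled", {
  ridge <- list(
    fn = function(logp) 50 * (logp[["a"]] + logp[["b"]])^2,
    values = c(a = 0.5, b = -0.5),
    lower = c(a = -3, b = -3), upper = c(a = 3, b = 3),
    freeNames = c("a", "b"))
  out <- iterativeFixing(ridge, nStarts = 15, seed = 4, maxIterations = 3)
  expect_identical(out$status, "stalled")
  expect_identical(nrow(out$ledger), 0L)
})
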