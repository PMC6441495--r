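test_that("chi-squared is the weighted sum of squared residuals", {
  # a single engineered data point: residual 1, sigma 0.5 -> chi2 = 4
  m <- gtModelV()
  p <- groundTruthParams("V")
  st <- initialState(m, m@conditions$arsenite, p)
  v0 <- st[["TSC2_pT1462"]]
  d <- data.frame(condition = "arsenite", readout = "TSC2_pT1462",
                  time_min = 0, mean = v0 + 1, sem = 0.5, n_reps = 3)
  prob <- fitProblem(m, timeCourseDataset(d), freeNames = "k_aa",
                     normalize = "none")
  expect_equal(chi2Objective(prob, log10(p[["k_aa"]])), 4, tolerance = 1e-8)
})

test_that("chi-squared is invariant to dataset record order", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  ds <- syntheticStudy(seed = 13)
  lp <- log10(p[c("k_stress_PI3K", "k_stress_Akt_S473")])
  v1 <- chi2Objective(fitProblem(m, ds, freeNames = names(lp)), lp)
  set.seed(1)
  shuffled <- timeCourseDataset(tcData(ds)[sample(nrow(tcData(ds))), ])
  v2 <- chi2Objective(fitProblem(m, shuffled, freeNames = names(lp)), lp)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("generator and objective are mutually consistent at the truth", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  free <- c("k_stress_PI3K", "k_stress_Akt_S473", "k_stress_mTORC1")
  lp <- log10(p[free])
  # normalized study
  prob <- fitProblem(m, noiseFreeStudy(), freeNames = free)
  expect_lt(chi2Objective(prob, lp), 1e-6)
  # raw study, raw objective
  probr <- fitProblem(m, rawStudy(), freeNames = free, normalize = "none")
  expect_lt(chi2Objective(probr, lp), 1e-6)
})

test_that("Latin hypercube starts stratify every free dimension", {
  b <- list(lower = c(a = -5, b = -2, c = 1), upper = c(a = 3, b = -2, c = 2))
  s <- lhsStarts(b, 4, seed = 3)
  expect_identical(dim(s), c(4L, 3L))
  # four draws occupy the four equal-width bins of [-5, 3] exactly once
  bins <- findInterval(s[, "a"], seq(-5, 3, by = 2), rightmost.closed = TRUE)
  expect_setequal(bins, 1:4)
  # degenerate bounds: held constant
  expect_identical(unique(s[, "b"]), -2)
  expect_identical(s, lhsStarts(b, 4, seed = 3))
  expect_false(identical(s, lhsStarts(b, 4, seed = 4)))
  # problem interface: dimensions follow the free parameters
  m <- gtModelV()
  prob <- fitProblem(m, noiseFreeStudy(),
                     freeNames = c("k_aa", "k_stress_PI3K"))
  s2 <- lhsStarts(prob, 10, seed = 1)
  expect_identical(dim(s2), c(10L, 2L))
  expect_true(all(s2[, "k_stress_PI3K"] <= -2))
})

test_that("the truth is a fixed point of the multistart optimizer", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  free <- c("k_stress_PI3K", "k_stress_Akt_S473")
  prob <- fitProblem(m, noiseFreeStudy(), freeNames = free)
  fit <- fitMultistart(prob, nStarts = 1,
                       starts = matrix(log10(p[free]), nrow = 1))
  best <- bestFit(fit)
  expect_true(best$converged)
  expect_lt(best$chi2, 1e-6)
  expect_equal(unname(10^best$logp), unname(p[free]), tolerance = 1e-3)
})

test_that("all starts are retained and sorted by fit quality", {
  m <- gtModelV()
  prob <- fitProblem(m, noiseFreeStudy(),
                     freeNames = c("k_stress_PI3K", "k_stress_Akt_S473"))
  fit <- fitMultistart(prob, nStarts = 5, seed = 2, maxit = 25)
  r <- fitResults(fit)
  expect_identical(nrow(r), 5L)
  expect_identical(sort(r$start_index), 1:5)
  expect_false(is.unsorted(r$chi2))
  # seeded bitwise reproducibility
  fit2 <- fitMultistart(prob, nStarts = 5, seed = 2, maxit = 25)
  expect_identical(fitResults(fit), fitResults(fit2))
  expect_identical(fit@par, fit2@par)
})

test_that("an added stress input can only improve the attainable fit", {
  ds <- syntheticStudy(gtModelIII(), groundTruthParams("III"), seed = 17)
  fitv <- function(variant, free) {
    m <- setParameterValues(buildModel(variant), groundTruthParams(variant))
    prob <- fitProblem(m, ds, freeNames = free)
    bestFit(fitMultistart(prob, nStarts = 6, seed = 3, maxit = 50))$chi2
  }
  chi2_II <- fitv("II", "k_stress_PI3K")
  chi2_III <- fitv("III", c("k_stress_PI3K", "k_stress_Akt_S473"))
  expect_lte(chi2_III, chi2_II + 1e-3)
})

test_that("best-fit chi-squared grows with the noise level", {
  m <- gtModelV()
  free <- c("k_stress_PI3K", "k_stress_Akt_S473")
  med <- vapply(c(0, 0.1, 0.2), function(cv) {
    stats::median(vapply(1:3, function(s) {
      ds <- syntheticStudy(seed = 30 + s, cv = cv, companions = FALSE)
      prob <- fitProblem(m, ds, freeNames = free)
      bestFit(fitMultistart(prob, nStarts = 3, seed = s, maxit = 40))$chi2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("extent of inhibition recovers engineered slope ratios", {
  tt <- defaultTimes()
  mkds <- function(lab, slope, sem = 0.01, n = 4)
    timeCourseDataset(data.frame(
      condition = lab, readout = "TSC2_pT1462", time_min = tt,
      mean = 0.1 + slope * tt, sem = sem, n_reps = n))
  ctl <- mkds("carrier", 0.01)
  expect_equal(extentOfInhibition(ctl, mkds("mk", 0.0017), "TSC2_pT1462"),
               0.83, tolerance = 1e-8)
  # identical induction: no inhibition
  expect_equal(extentOfInhibition(ctl, mkds("same", 0.01), "TSC2_pT1462"), 0)
  # flat treated course with honest replicate scatter: the ANOVA rule fires
  flat <- timeCourseDataset(data.frame(
    condition = "wort", readout = "Akt_pT308", time_min = tt,
    mean = 0.1 + c(0.001, -0.002, 0.002, -0.001, 0.001, -0.001),
    sem = 0.05, n_reps = 4))
  ctl2 <- timeCourseDataset(data.frame(
    condition = "carrier", readout = "Akt_pT308", time_min = tt,
    mean = 0.1 + 0.01 * tt, sem = 0.01, n_reps = 4))
  expect_identical(extentOfInhibition(ctl2, flat, "Akt_pT308"), 1.0)
  # a control without positive induction cannot anchor the comparison
  falling <- mkds("ctl_fall", -0.001)
  expect_error(extentOfInhibition(falling, ctl, "TSC2_pT1462"),
               "no positive induction")
  expect_error(extentOfInhibition(ctl, mkds("mk", 0.0017), "p70_S6K_pT389"),
               "absent")
})

test_that("extent is clipped into the unit interval", {
  tt <- defaultTimes()
  mk <- function(lab, slope) timeCourseDataset(data.frame(
    condition = lab, readout = "TSC2_pT1462", time_min = tt,
    mean = 0.5 + slope * tt, sem = 0.02, n_reps = 4))
  # super-induction in the treated arm floors at 0
  expect_identical(extentOfInhibition(mk("c", 0.005), mk("t", 0.02),
                                      "TSC2_pT1462"), 0)
  # negative treated slope caps at 1
  expect_identical(extentOfInhibition(mk("c", 0.005), mk("t", -0.004),
                                      "TSC2_pT1462"), 1)
})
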