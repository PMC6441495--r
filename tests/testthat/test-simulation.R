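test_that("initial state honours the zero-start and fraction conventions", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  st <- initialState(m, m@conditions$arsenite, p)
  expect_identical(unname(st[c("Akt_pT308_pS473", "PRAS40_pT246_pS183",
                               "p70_S6K_pT229_pT389", "IR_beta_pY1146")]),
                   rep(0, 4))
  # wortmannin Akt_pT308 initial = fraction x arsenite-specific initial
  stw <- initialState(m, m@conditions$arsenite_wortmannin, p)
  expect_equal(unname(stw["Akt_pT308"]),
               p[["ic_frac_Akt_pT308.arsenite_wortmannin"]] *
                 p[["ic_Akt_pT308.arsenite"]])
  p2 <- p
  p2["ic_frac_Akt_pT308.arsenite_wortmannin"] <- 0.5
  p2["ic_Akt_pT308.arsenite"] <- 0.2
  expect_equal(unname(initialState(m, m@conditions$arsenite_wortmannin,
                                   p2)["Akt_pT308"]), 0.1)
  # pool total equals the sum of the member initials
  expect_equal(sum(st[conservationPools()$Akt]),
               p[["ic_Akt.arsenite"]] + p[["ic_Akt_pT308.arsenite"]] +
                 p[["ic_Akt_pS473.arsenite"]])
  expect_error(initialState(m, stressCondition("unknown_condition"), p),
               "initial-concentration")
})

test_that("a fully dephosphorylated unstressed system stays constant", {
  m <- buildModel("I", conditions = list(basal = stressCondition(
    "basal", stress = FALSE)))
  p <- parameterValues(m)
  # all phospho/localized initials zero, unphosphorylated pools at 1
  p[grep("^ic_", names(p))] <- 0
  for (sp in c("IR_beta", "IRS1", "PI3K", "PDK1_cyt", "Akt", "TSC2",
               "PRAS40", "p70_S6K", "4EBP1"))
    p[sprintf("ic_%s.basal", sp)] <- 1
  traj <- simulateModel(m, m@conditions$basal, p)
  expect_lt(max(abs(sweep(traj[, -1], 2, traj[1, -1]))), 1e-12)
})

test_that("the engine reproduces the analytic single-cycle solution", {
  # PI3K cycle with a constant IRS1_loc drive: everything else silenced
  m <- buildModel("I", conditions = list(basal = stressCondition(
    "basal", stress = FALSE)))
  p <- parameterValues(m)
  p[] <- 0
  p["k_PI3K_act"] <- 0.008
  p["k_PI3K_dephos"] <- 0.1
  p["ic_IRS1.basal"] <- 0.5
  p["ic_IRS1_loc.basal"] <- 0.5    # A_IRS1 = 0.5 throughout
  p["ic_PI3K.basal"] <- 1
  times <- seq(0, 60, by = 5)
  traj <- simulateModel(m, m@conditions$basal, p, times = times)
  kon <- 0.008 * 0.5; koff <- 0.1
  closed <- (kon / (kon + koff)) * (1 - exp(-(kon + koff) * times))
  expect_lt(max(abs(traj[, "PI3K_p"] - closed)[-1] / closed[-1]), 1e-6)
})

test_that("integration is deterministic and tolerance-consistent", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  cond <- m@conditions$arsenite
  t1 <- simulateModel(m, cond, p)
  t2 <- simulateModel(m, cond, p)
  expect_identical(t1, t2)
  t3 <- simulateModel(m, cond, p, rtol = 2e-8, atol = 2e-10)
  expect_lt(max(abs(t3 - t1) / pmax(abs(t1), 1e-3)), 1e-4)
  expect_error(simulateModel(m, cond, p, times = c(1, 5)), "start at 0")
  expect_error(simulateModel(m, cond, p, rtol = -1), "positive")
})

test_that("compiled and reference right-hand sides integrate identically", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  for (lab in c("arsenite", "arsenite_wortmannin", "arsenite_mk2206")) {
    tC <- simulateModel(m, m@conditions[[lab]], p, times = c(0, 10, 60))
    tR <- simulateModel(m, m@conditions[[lab]], p, times = c(0, 10, 60),
                        engine = "R")
    expect_lt(max(abs(tC - tR)), 1e-7)
  }
})

test_that("pool conservation holds along trajectories of every variant", {
  set.seed(11)
  p5 <- groundTruthParams("V")
  for (v in c("I", "II", "III", "IV", "V")) {
    m <- buildModel(v)
    p <- p5[parameterTable(m)$name]
    traj <- simulateModel(m, m@conditions$arsenite, p)
    for (mem in conservationPools()) {
      s <- rowSums(traj[, mem, drop = FALSE])
      expect_lt(max(abs(s - s[1])), 1e-6)
    }
  }
})

test_that("observables are the defined summand totals", {
  m <- gtModelV()
  st <- rep(0, 25)
  names(st) <- speciesNames()
  st["Akt_pS473"] <- 0.1
  st["Akt_pT308_pS473"] <- 0.05
  traj <- rbind(c(time = 0, st))
  ob <- computeObservables(m, traj)
  expect_identical(nrow(ob), 9L)
  expect_equal(ob$value[ob$observable == "Akt_pS473"], 0.15)
  expect_equal(ob$value[ob$observable == "Akt_pT308"], 0.05)
  expect_equal(sum(ob$value[!ob$observable %in%
                              c("Akt_pT308", "Akt_pS473")]), 0)
  # all-zero phospho state maps to nine zeros
  traj0 <- rbind(c(time = 0, stats::setNames(rep(0, 25), speciesNames())))
  expect_identical(sum(abs(computeObservables(m, traj0)$value)), 0)
})

test_that("inhibitors cannot raise mTORC1 output", {
  p <- groundTruthParams("V")
  for (v in c("II", "V")) {
    m <- buildModel(v)
    pv <- p[parameterTable(m)$name]
    avg <- function(cond) {
      traj <- simulateModel(m, cond, pv)
      mean(traj[, "p70_S6K_pT389"] + traj[, "p70_S6K_pT229_pT389"])
    }
    expect_lte(avg(m@conditions$arsenite_wortmannin),
               avg(m@conditions$arsenite))
  }
  # MK-2206 comparison, for a variant where S473-only Akt is active
  m3 <- gtModelIII()
  p3 <- groundTruthParams("III")
  avg3 <- function(cond) {
    traj <- simulateModel(m3, cond, p3)
    mean(traj[, "p70_S6K_pT389"] + traj[, "p70_S6K_pT229_pT389"])
  }
  expect_lte(avg3(m3@conditions$arsenite_mk2206),
             avg3(m3@conditions$arsenite))
})

test_that("trajectories export as tidy CSV", {
  m <- gtModelV()
  traj <- simulateModel(m, m@conditions$arsenite, groundTruthParams("V"))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  out <- exportTrajectory(m, traj, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("condition", "series_type", "name", "time_min", "value"))
  expect_setequal(unique(back$series_type), c("species", "observable"))
  expect_identical(nrow(back), (25L + 9L) * nrow(traj))
})
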