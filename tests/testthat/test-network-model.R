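test_that("canonical species and conserved pools partition the network", {
  sp <- speciesNames()
  expect_length(sp, 25)
  expect_false(anyDuplicated(sp) > 0)
  pools <- conservationPools()
  expect_length(pools, 9)
  expect_setequal(unlist(pools, use.names = FALSE), sp)
  expect_identical(sum(lengths(pools)), 25L)
})

test_that("variant construction sets stress inputs and Akt activity flags", {
  n_stress <- function(m) sum(!is.na(reactionTable(m)$stress_param)) +
    ("k_stress_mTORC1" %in% parameterTable(m)$name)
  expect_identical(vapply(c("I", "II", "III", "IV", "V"),
                          function(v) n_stress(buildModel(v)), numeric(1)),
                   c(I = 0, II = 1, III = 2, IV = 2, V = 3))
  expect_true(buildModel("I")@sFlag)
  expect_true(buildModel("III")@sFlag)
  expect_false(buildModel("IV")@sFlag)
  expect_false(buildModel("V")@sFlag)
  # III and IV share the identical reaction list; only the activity
  # definition differs
  expect_identical(reactionTable(buildModel("III")),
                   reactionTable(buildModel("IV")))
  expect_error(buildModel("VI"), "valid tags")
  # reaction set identical across variants up to stress attachments
  strip <- function(m) {
    rt <- reactionTable(m); rt$stress_param <- NULL; rt
  }
  expect_identical(strip(buildModel("I")), strip(buildModel("V")))
})

test_that("model V counts 25 species and 91 free parameters", {
  m <- buildModel("V")
  expect_length(speciesNames(m), 25)
  expect_identical(nFreeParameters(m), 91L)
})

test_that("candidate enumeration returns the 37 augmentable conversions", {
  cand <- candidateStressTargets(buildModel("II"))
  expect_identical(nrow(cand), 37L)
  key <- paste(cand$substrate, cand$product, sep = ">")
  expect_false(anyDuplicated(key) > 0)
  expect_true("Akt>Akt_pS473" %in% key)
  expect_true("Akt_pT308>Akt_pT308_pS473" %in% key)
  expect_false("PI3K>PI3K_p" %in% key)
  # enumeration is defined for the single-input base model only
  expect_error(candidateStressTargets(buildModel("III")), "stress inputs")
  expect_error(candidateStressTargets(buildModel("V")), "stress inputs")
})

test_that("withStressInput adds exactly one parameter and leaves the base untouched", {
  m2 <- buildModel("II")
  before <- parameterTable(m2)
  m3 <- withStressInput(m2, "Akt", "Akt_pS473")
  expect_identical(nFreeParameters(m3), nFreeParameters(m2) + 1L)
  expect_identical(parameterTable(m2), before)
  # augmented topology matches the canonical model III stress attachments
  canon <- reactionTable(buildModel("III"))
  got <- reactionTable(m3)
  expect_identical(!is.na(got$stress_param), !is.na(canon$stress_param))
  expect_error(withStressInput(m2, "Akt", "TSC2_pT1462"), "no reaction")
  expect_error(withStressInput(m2, "PI3K", "PI3K_p"), "first stress input")
  expect_error(withStressInput(m3, "Akt", "Akt_pS473"), "already carries")
  # composing two further inputs (Akt-pS473, then mTORC1) gives three inputs
  mv <- withStressInput(m3, "mTORC1")
  expect_identical(sum(!is.na(reactionTable(mv)$stress_param)) +
                     ("k_stress_mTORC1" %in% parameterTable(mv)$name), 3L)
})

test_that("right-hand side vanishes on the empty state and conserves pools", {
  m <- buildModel("I")
  expect_identical(max(abs(evaluateRHS(m, rep(0, 25)))), 0)
  # pool sums of the derivative vanish for random states and parameters
  set.seed(42)
  for (v in c("II", "V")) {
    mv <- buildModel(v)
    for (rep in 1:5) {
      st <- randomState()
      pp <- randomParams(mv)
      dx <- evaluateRHS(mv, st, pp, stressCondition("arsenite"))
      sums <- vapply(conservationPools(), function(mem) sum(dx[mem]),
                     numeric(1))
      expect_lt(max(abs(sums)), 1e-12)
    }
  }
})

test_that("right-hand side rejects bad states and parameters", {
  m <- buildModel("I")
  st <- rep(0, 25); st[1] <- -1e-3
  expect_error(evaluateRHS(m, st), "negative state")
  p <- parameterValues(m); p[1] <- NaN
  expect_error(evaluateRHS(m, rep(0.1, 25), p), "non-finite")
})

test_that("single activation cycle matches a hand-enumerated flux table", {
  # isolated PI3K cycle: stress drive k_on = 0.2/min, deactivation
  # k_off = 0.1/min; every other rate constant silenced
  m <- buildModel("II")
  p <- parameterValues(m)
  p[] <- 0
  p["k_stress_PI3K"] <- 0.2
  p["k_PI3K_dephos"] <- 0.1
  cond <- stressCondition("arsenite")
  oracle <- function(x, xp) c(-0.2 * x + 0.1 * xp, 0.2 * x - 0.1 * xp)
  for (x in c(0, 0.25, 1)) for (xp in c(0, 0.4, 1)) {
    st <- rep(0, 25); st[6] <- x; st[7] <- xp
    dx <- evaluateRHS(m, st, p, cond)
    expect_equal(unname(dx[c("PI3K", "PI3K_p")]), oracle(x, xp),
                 tolerance = 1e-14)
    expect_identical(max(abs(dx[-c(6, 7)])), 0)
  }
})

test_that("stress-free model V collapses onto its nested variants", {
  set.seed(7)
  m1 <- buildModel("I"); m4 <- buildModel("IV"); m5 <- buildModel("V")
  p5 <- randomParams(m5)
  p5[c("k_stress_PI3K", "k_stress_Akt_S473", "k_stress_mTORC1")] <- 0
  p4 <- p5[parameterTable(m4)$name]
  p1 <- p5[parameterTable(m1)$name]
  cond <- stressCondition("arsenite")
  for (rep in 1:5) {
    st <- randomState()
    # same Akt activity convention: V(no stress) equals IV on any state
    expect_equal(evaluateRHS(m5, st, p5, cond),
                 evaluateRHS(m4, st, p4, cond), tolerance = 1e-14)
    # with the S473-only species empty, the variants' Akt conventions
    # coincide and V(no stress) equals model I
    st0 <- st; st0["Akt_pS473"] <- 0
    expect_equal(evaluateRHS(m5, st0, p5, cond),
                 evaluateRHS(m1, st0, p1, cond), tolerance = 1e-14)
  }
})

test_that("model IV equals model III on states without S473-only Akt", {
  set.seed(8)
  m3 <- buildModel("III"); m4 <- buildModel("IV")
  p <- randomParams(m3)
  cond <- stressCondition("arsenite")
  for (rep in 1:5) {
    st <- randomState(); st["Akt_pS473"] <- 0
    expect_equal(evaluateRHS(m3, st, p, cond), evaluateRHS(m4, st, p, cond),
                 tolerance = 1e-14)
  }
})

test_that("inhibitors follow the Boolean-like contract exactly", {
  m <- gtModelV()
  p <- groundTruthParams("V")
  st <- randomState()
  # wortmannin: the PI3K activation flux is exactly zero, so the PI3K_p
  # derivative reduces to its deactivation term
  wrt <- stressCondition("arsenite_wortmannin", wortmannin = TRUE,
                         icBlock = "arsenite")
  dx <- evaluateRHS(m, st, p, wrt)
  expect_equal(unname(dx["PI3K_p"]),
               -p[["k_PI3K_dephos"]] * st[["PI3K_p"]], tolerance = 1e-14)
  # MK-2206 scales every Akt-driven flux by exactly 1 - 0.83
  plain <- stressCondition("arsenite")
  mk <- stressCondition("arsenite_mk2206", mk2206 = TRUE,
                        icBlock = "arsenite")
  st0 <- st
  st0["TSC2_pT1462"] <- 0   # isolate the forward Akt-driven TSC2 flux
  d_plain <- evaluateRHS(m, st0, p, plain)
  d_mk <- evaluateRHS(m, st0, p, mk)
  expect_equal(unname(d_mk["TSC2_pT1462"] / d_plain["TSC2_pT1462"]),
               1 - 0.83, tolerance = 1e-12)
})

test_that("plain-text model summary lists species, reactions and parameters", {
  lines <- capture.output(modelSummary(buildModel("II")))
  expect_true(any(grepl("== Species ==", lines)))
  expect_true(any(grepl("== Reactions ==", lines)))
  expect_true(any(grepl("k_PI3K_act", lines)))
})
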