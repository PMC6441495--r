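# Rate-law algebra.
#
# Every reaction contributes the flux
#   v = k * multiplicity * [substrate] * A_modifier   (+ k_stress * u * [substrate])
# where A_modifier is a dimensionless fractional-occupancy activity:
#   A_PI3K   = [PI3K_p] / C_PI3K            (also drives mTORC2, which is implicit)
#   A_PDK1   = [PDK1_mem] / C_PDK1
#   A_Akt    = ([Akt_pT308] + s*[Akt_pS473] + 2*[Akt_pT308_pS473]) / C_Akt
#              (s = 1 for variants I-III, 0 for IV/V; additive site effects;
#               scaled by 1 - 0.83 under MK-2206)
#   A_S6K    = ([p70_S6K_pT389] + [p70_S6K_pT229_pT389]) / C_S6K
#   A_IR     = [IR_beta_pY1146] / C_IR
#   A_IRS1   = [IRS1_loc] / C_IRS1          (basal drive of PI3K activation)
#   A_mTORC1 = (k_aa*u_aa + k_stress_mTORC1*u_stress)
#              * (1 - [TSC2]/C_TSC2) * (1 - [PRAS40]/C_PRAS40)
#              (concentration-dependent inhibition by the unphosphorylated
#               inhibitors; phosphorylation at any site relieves inhibition)
# Wortmannin zeroes the whole PI3K activation flux (basal and stress term);
# pool totals C are the conserved moiety sums of the supplied state.

.MODIFIER_CODES <- c(none = 0, mTORC2 = 1, PDK1 = 2, Akt = 3, mTORC1 = 4,
                     S6K = 5, IR = 6, IRS1 = 7, insulin = 8, PI3K = 9)

.poolTotals <- function(state) {
  vapply(.MTOR_POOLS, function(m) sum(state[m]), numeric(1))
}

.frac <- function(num, den) if (den > 0) num / den else 0

# all activity values for a state under a condition
.activities <- function(model, state, params, condition) {
  C <- .poolTotals(state)
  u_stress <- as.numeric(condition@stress)
  a_pi3k <- .frac(state[["PI3K_p"]], C[["PI3K"]])
  a_akt <- .frac(state[["Akt_pT308"]] +
                   (if (model@sFlag) 1 else 0) * state[["Akt_pS473"]] +
                   2 * state[["Akt_pT308_pS473"]], C[["Akt"]])
  if (condition@mk2206) a_akt <- a_akt * (1 - model@mkExtent)
  k <- stats::setNames(model@parameters$value, model@parameters$name)
  pre_c1 <- k[["k_aa"]] * condition@aa +
    (if ("k_stress_mTORC1" %in% names(k))
       k[["k_stress_mTORC1"]] * u_stress else 0)
  c(none    = 1,
    mTORC2  = a_pi3k,
    PDK1    = .frac(state[["PDK1_mem"]], C[["PDK1"]]),
    Akt     = a_akt,
    mTORC1  = pre_c1 *
      max(0, 1 - .frac(state[["TSC2"]], C[["TSC2"]])) *
      max(0, 1 - .frac(state[["PRAS40"]], C[["PRAS40"]])),
    S6K     = .frac(state[["p70_S6K_pT389"]] + state[["p70_S6K_pT229_pT389"]],
                    C[["p70_S6K"]]),
    IR      = .frac(state[["IR_beta_pY1146"]], C[["IR"]]),
    IRS1    = .frac(state[["IRS1_loc"]], C[["IRS1"]]),
    insulin = condition@insulin,
    PI3K    = a_pi3k)
}

#' Evaluate the ODE right-hand side
#'
#' Reference (pure R) evaluation of the time-derivative vector under
#' mass-action kinetics with fractional-occupancy modifier activities and
#' Boolean-like inhibitor semantics. The compiled integrator used by
#' [simulateModel()] implements the same algebra; the two agree to machine
#' precision.
#'
#' @param model An [MTORModel-class] object.
#' @param state Numeric vector of 25 species concentrations (a.u.), in
#'   canonical order (names optional).
#' @param params Named parameter vector on the natural scale; defaults to the
#'   model's current values.
#' @param condition A [StressCondition-class]; defaults to plain arsenite
#'   stress.
#' @param t Time in minutes (the system is autonomous; the stress step is
#'   encoded in `condition`).
#' @return Named numeric vector of derivatives (a.u./min).
#' @export
#' @examples
#' m <- buildModel("I")
#' evaluateRHS(m, rep(0, 25))  # all-zero state, all-zero derivative
evaluateRHS <- function(model, state, params = parameterValues(model),
                        condition = stressCondition("arsenite"), t = 0) {
  stopifnot(is(model, "MTORModel"), length(state) == 25L)
  if (any(!is.finite(params)))
    stop("non-finite parameter values", call. = FALSE)
  if (any(state < -1e-8))
    stop("negative state entries beyond tolerance", call. = FALSE)
  state <- pmax(as.numeric(state), 0)
  names(state) <- model@species
  model <- setParameterValues(model, params)
  k <- stats::setNames(model@parameters$value, model@parameters$name)
  act <- .activities(model, state, params, condition)
  u_stress <- as.numeric(condition@stress)
  rt <- model@reactions
  dx <- stats::setNames(numeric(25), model@species)
  for (i in seq_len(nrow(rt))) {
    if (condition@wortmannin && rt$wortmannin_sensitive[i]) next
    v <- k[[rt$param[i]]] * rt$multiplicity[i] * state[[rt$substrate[i]]] *
      act[[rt$modifier[i]]]
    sp <- rt$stress_param[i]
    if (!is.na(sp)) v <- v + k[[sp]] * u_stress * state[[rt$substrate[i]]]
    dx[rt$substrate[i]] <- dx[rt$substrate[i]] - v
    dx[rt$product[i]] <- dx[rt$product[i]] + v
  }
  dx
}

# Pack model + params + condition into the flat parameter vector consumed by
# the compiled right-hand side (src/mtor_rhs.c). Layout:
#   [1] n_reactions, [2] s flag, [3:11] pool totals, [12] mTORC1 activity
#   prefactor, [13] insulin level, then 5 slots per reaction:
#   substrate index (0-based), product index, effective rate constant
#   (multiplicity, MK-2206 scaling and wortmannin zeroing folded in),
#   modifier code, effective stress rate (u_stress and wortmannin folded in).
.NPARMS <- 256L

.packParms <- function(model, params, condition, state0) {
  k <- params
  rt <- model@reactions
  sp_idx <- stats::setNames(seq_along(model@species) - 1L, model@species)
  C <- .poolTotals(stats::setNames(as.numeric(state0), model@species))
  u_stress <- as.numeric(condition@stress)
  pre_c1 <- k[["k_aa"]] * condition@aa +
    (if ("k_stress_mTORC1" %in% names(k))
       k[["k_stress_mTORC1"]] * u_stress else 0)
  out <- numeric(.NPARMS)
  nr <- nrow(rt)
  out[1] <- nr
  out[2] <- if (model@sFlag) 1 else 0
  out[3:11] <- C
  out[12] <- pre_c1
  out[13] <- condition@insulin
  keff <- k[rt$param] * rt$multiplicity
  keff[rt$mk_sensitive] <- keff[rt$mk_sensitive] *
    (if (condition@mk2206) 1 - model@mkExtent else 1)
  kstr <- ifelse(is.na(rt$stress_param), 0,
                 k[ifelse(is.na(rt$stress_param), "k_aa", rt$stress_param)] *
                   u_stress)
  if (condition@wortmannin) {
    keff[rt$wortmannin_sensitive] <- 0
    kstr[rt$wortmannin_sensitive] <- 0
  }
  base <- 13 + 5 * (seq_len(nr) - 1)
  out[base + 1] <- sp_idx[rt$substrate]
  out[base + 2] <- sp_idx[rt$product]
  out[base + 3] <- keff
  out[base + 4] <- .MODIFIER_CODES[rt$modifier]
  out[base + 5] <- kstr
  out
}
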