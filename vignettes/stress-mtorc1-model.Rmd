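---
title: "Modelling stress signaling to mTORC1: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stress signaling to mTORC1: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtorStress)
```

## The model

Arsenite stress activates mTORC1 signaling in serum-starved cells, and the
question the modelling answers is *where* the stress signal enters the
PI3K/Akt/TSC/mTORC1 network. `mtorStress` implements this as a family of
five nested ODE models over 25 species grouped into 9 conserved pools
(IR-β, IRS1, PI3K, PDK1, Akt, TSC2, PRAS40, p70-S6K, 4E-BP1; each pool is
the set of phosphorylation/localization variants of one protein, summing to
a constant total). The mTOR complexes are implicit: mTORC1 and mTORC2 are
represented by the fluxes they catalyse, not by dynamic species.

Every conversion follows mass-action kinetics,

$$v \;=\; k \cdot m \cdot [\mathrm{substrate}] \cdot A_{\mathrm{modifier}}
\;+\; k_{\mathrm{stress}} \, u_{\mathrm{stress}}(t) \, [\mathrm{substrate}],$$

where $m \in \{1, 2\}$ doubles the rate of the second phosphorylation of an
AGC-kinase site pair relative to the first (which shares the same rate
constant), and $A$ is a dimensionless fractional-occupancy activity:

* $A_{\mathrm{PI3K}} = [\mathrm{PI3K_p}]/C_{\mathrm{PI3K}}$, which also
  drives the implicit mTORC2;
* $A_{\mathrm{PDK1}} = [\mathrm{PDK1_{mem}}]/C_{\mathrm{PDK1}}$;
* $A_{\mathrm{Akt}} = ([\mathrm{pT308}] + s\,[\mathrm{pS473}] +
  2\,[\mathrm{pT308{+}pS473}])/C_{\mathrm{Akt}}$ — additive site effects;
  the flag $s$ encodes whether Akt phosphorylated *only* at S473 is active
  towards the mTORC1 inhibitors ($s = 1$ in variants I–III, $s = 0$ in IV
  and V);
* $A_{\mathrm{S6K}}$ counts only T389-containing species;
* $A_{\mathrm{mTORC1}} = (k_{aa} u_{aa} + k^{C1}_{\mathrm{stress}}
  u_{\mathrm{stress}})\,(1 - [\mathrm{TSC2}]/C_{\mathrm{TSC2}})
  (1 - [\mathrm{PRAS40}]/C_{\mathrm{PRAS40}})$ — concentration-dependent
  inhibition: a fully unphosphorylated inhibitor pool shuts mTORC1 off
  completely, and phosphorylation at *any* site relieves inhibition (only
  the fully unphosphorylated TSC2 and PRAS40 species inhibit).

The published equation sheet for this network is only available as images,
so the algebra above is this package's own concrete realization of the
stated modelling principles (mass action, fractional-occupancy modifiers,
multiplicative inhibition). One link required a choice the activity list
leaves open: the basal catalyst of PI3K activation, which we take to be
membrane-localized IRS1, $A_{\mathrm{IRS1}} =
[\mathrm{IRS1_{loc}}]/C_{\mathrm{IRS1}}$, per the pathway narrative (IRS1
recruits and activates PI3K). Reconciling against the deposited SBML model
(BioModels MODEL1902140002, user-supplied file) remains the definitive
check; `importSBML()` deliberately supports only this package's own SBML
dialect, so that comparison is a manual exercise.

Inhibitors follow a Boolean-like scheme: wortmannin zeroes the whole PI3K
activation flux (basal and stress term); MK-2206 scales $A_{\mathrm{Akt}}$
by $1 - 0.83$, the fixed partial extent estimated from induction-slope
ratios (see below). Inputs are constant on the simulated window: arsenite
is a unit step at $t = 0$ ($u_{\mathrm{stress}}$), amino acids are present
throughout ($u_{aa} = 1$, cells in full medium), and insulin is zero
(overnight starvation), which makes the IR arm structurally silent — it is
retained because it carries the S6K→IRS1-pS636 feedback observable.

### The five variants

| variant | stress inputs | S473-only Akt active ($s$) |
|---|---|---|
| I | none | yes |
| II | PI3K | yes |
| III | PI3K, Akt→Akt-pS473 | yes |
| IV | PI3K, Akt→Akt-pS473 | no |
| V | PI3K, Akt→Akt-pS473, mTORC1 | no |

The reaction set is identical across variants — only stress-term
attachments and $s$ differ — so variants are nested: `buildModel("V")`
with all stress strengths at 0 has the same right-hand side as model IV,
and coincides with model I on states without S473-only Akt.

### Parameters and the 91-parameter decomposition

Model V carries 91 free parameters:

* 24 fitted reaction rate constants (26 in the table, of which 2 are
  structurally dead under starvation — IR-β phosphorylation, driven by
  insulin = 0, and IRS1 membrane recruitment, driven by IR-β-pY1146 which
  starts at zero and can never rise — and are therefore present but fixed);
* the amino-acid drive $k_{aa}$ and 3 stress-input strengths;
* 21 condition-specific initial concentrations × 3 conditions = 63. All
  species start free except the three double-phosphorylated ones and
  IR-β-pY1146, which are zero at the starved baseline; the wortmannin
  condition's Akt-pT308 initial is a fraction ∈ [0, 1] of the
  arsenite-specific initial (one parameter either way).

Bounds are log10-uniform by class: mass-action rates $[10^{-5}, 10^{1}]$,
PI3K-activation rates $[10^{-5}, 10^{-2}]$ (preventing unrealistically
step-like activation of the unobserved PI3K species), initial
concentrations $[10^{-5}, 10^{1}]$, input strengths $[10^{-5}, 10^{3}]$.
Units: minutes, arbitrary concentration units (a.u.); activities are
dimensionless.

## Simulation

`simulateModel()` integrates with `deSolve::lsoda` (stiff-capable) against
a compiled C right-hand side; `evaluateRHS()` is the readable pure-R
reference of the same algebra and the two are cross-checked in the test
suite. Defaults: output grid {0, 2.5, 5, 15, 30, 60} min (dense early,
matching the fast phosphorylation response), `rtol` 1e-8 / `atol` 1e-10
for simulation, relaxed to 1e-6/1e-8 inside the objective where the
integrator runs thousands of times. Concentrations in $(-10^{-8}, 0)$ are
clipped to zero; anything more negative raises an error. Pool sums are
conserved by construction (each reaction moves mass within one pool); the
tests require conservation to 1e-6 along trajectories.

## The synthetic study

`generateDataset()` emulates quantified immunoblot time courses: the nine
observables (site-specific antibody signals, each the sum of every species
carrying the site) are sampled on the output grid, each replicate is
multiplied pointwise by i.i.d. log-normal factors with unit mean and
coefficient of variation `cv`, then normalized to its own mean across the
time course — the same per-replicate normalization applied to real blot
quantifications. Means and SEMs are taken across replicates. Defaults: 3
conditions × 9 readouts × 6 time points × 4 replicates, `cv = 0.15` (a
typical immunoblot replicate CV). Log-normal noise reflects positive,
roughly scale-proportional intensities; additive Gaussian noise is
available behind a flag.

The pinned ground truth (`groundTruthParams()`) is a documented model V
regime chosen so the synthetic study reproduces the qualitative physiology
that motivates the modelling: arsenite induces ≥ 2-fold rises in
Akt-pT308, Akt-pS473, TSC2-pT1462 and p70-S6K-pT389 by 30–60 min, and
under wortmannin Akt-pS473 and p70-S6K-pT389 remain stress-inducible at
reduced amplitude (the PI3K-independent signal the input search must
find). Its baseline initials are the model's own relaxed no-stress state;
the inhibitor conditions' initials are that baseline integrated a further
30 min with the inhibitor present, i.e. the experimental pre-incubation
absorbed into condition-specific initials. The PI3K input strength sits at
its class cap ($10^{-2}$/min), making the PI3K arm the slow upstream
timescale.

What the generator does *not* emulate: densitometry and loading-control
artefacts, readout-specific replicate counts, correlated (gel-wise) noise,
and day effects. Passing recovery tests therefore demonstrate that the
machinery is correct and mutually consistent, not that real immunoblot
data are this benign.

Two artificial-data constructions mirror the study's devices:
`makeConstantDataset()` freezes every record at its $t = 0$ value under a
`_no_stress` label (fitted alongside the real data, it penalizes models
that produce dynamics without stress), and `wortmanninResidualDataset()`
restricts a wortmannin dataset to the four readouts whose residual
induction must be attributed to PI3K-independent inputs. Note that the
wortmannin no-stress companion is intrinsically imperfect even at the
generating parameters: a 30-min pre-incubation baseline is still relaxing,
so its "constant" data carry a small model-independent penalty shared by
every candidate in the search.

## Fitting

`chi2Objective()` is a weighted sum of squares,
$\chi^2 = \sum_i \left((s_i - \bar y_i)/\max(\mathrm{SEM}_i,
\sigma_{\min})\right)^2$ with $\sigma_{\min} = 0.05$ a.u. guarding
zero-SEM points. Because the data are per-replicate mean-normalized and no
observation-scale parameters are fitted, the simulated observables are
mean-normalized per (condition, readout) over the fitted time points —
exactly the data's normalization, which profiles the per-readout scale out
of the comparison; no-stress companions are normalized with their parent
condition's factors so that constancy, not scale, is what they constrain.
A `normalize = "none"` mode supports raw-concentration fitting (used by
the recovery experiments). Failed integrations return a penalty
$\chi^2 = 10^{12}$ and are flagged, so multistarts continue.

`fitMultistart()` draws Latin hypercube starts in log10 space
(`lhs::randomLHS`; every parameter's $n$ draws occupy $n$ equal-width bins
exactly once) and polishes each with L-BFGS-B under the class bounds,
finite-difference gradients. All starts are retained — failed ones
flagged, never dropped — and sorted by $\chi^2$. 500 starts reproduce the
original search scale; 25 is the desk-scale default used in the tests.

`extentOfInhibition()` implements the inhibitor-calibration rule: if the
treated time course shows no significant change across time points
(one-way ANOVA reconstructed from the per-time-point mean/SEM/n summary,
$\alpha = 0.05$), inhibition is complete (1.0, the wortmannin case);
otherwise the OLS induction slopes are compared,
$1 - b_{\mathrm{treated}}/b_{\mathrm{control}}$, clipped to $[0, 1]$ (0.83
for MK-2206). The slope window is the full 0–60 min course by default; the
original figure does not state its window, and on saturating courses a
full-window OLS slope underestimates the initial induction rate, which is
why the package validates this operation on constructed linear slope pairs
with known ratios rather than on its own saturating simulations.

## Input search and model selection

`secondInputSearch()` attaches a candidate arsenite input to each of the
37 substrate→product conversions of the single-input model II (every
conversion except the already-stressed PI3K activation), fits each
augmented model by multistart, and ranks candidates by information
criteria computed on the $\chi^2$ scale (the convention of ODE calibration
toolboxes; $\chi^2$ stands in for $-2\log L$ up to a data-dependent
constant shared by all models on the same data, so rankings are
unaffected):

$$\mathrm{AIC} = \chi^2 + 2k, \qquad
\mathrm{AICc} = \mathrm{AIC} + \tfrac{2k(k+1)}{n-k-1}, \qquad
\mathrm{BIC} = \chi^2 + k \ln n,$$

with $k$ the free-parameter count and $n$ the number of fitted means
(including the no-stress companion records), held identical across
compared models. A candidate is accepted only if it reduces AIC by at
least 5 % (`isImprovement()`), the gate that accepted the Akt→Akt-pS473
input (8788 → 1127, an 87 % reduction) and rejected the third input's gain
(1127 → 1109, 1.6 %) in the original analysis — both decisions are
recomputed from the shipped reference table at run time. Candidates are
fitted independently with seeds derived from their canonical index, so the
sorted table is independent of evaluation order and the search is
resumable per candidate. The third (mTORC1) input is placed by hypothesis,
not discovered by enumeration — the search space is single additional
inputs only.

**Desk-scale design.** The acceptance-level experiment runs the full
37-candidate search at 25 starts in 10 seeded replicates on data generated
from the model III truth under arsenite ± wortmannin (the discriminating
perturbation) with companions, holding kinetic and initial-concentration
parameters at the generating values so each candidate contributes exactly
one free parameter — a pure input-location scan. At this scale the true
candidate ranks first by a large margin; the variant-ordering property
AIC(V) < AIC(III) < AIC(II) on three-input data is checked the same way
with the stress strengths free. The paper-scale configuration (500 starts,
all 89–91 parameters free) uses the same API unchanged and is a matter of
compute, not code.

## Identifiability

`profileLikelihood()` steps one parameter from its optimum in both
directions, re-optimizing all other free parameters at each grid point
(warm-started L-BFGS-B), with adaptive steps targeting $\chi^2$ increments
of about a tenth of the threshold and at most 50 steps per direction. A
direction is "identifiable" if the re-optimized $\chi^2$ exceeds the
minimum by $\Delta\chi^2 = 3.84$ (95 % pointwise, 1 dof — the method
reference names no threshold, so the conventional one is used) before the
bound; hitting the bound first marks that side non-identifiable.
Re-optimization failures flag the point and the profile continues. A
parameter pinned at a bound (as the PI3K input strength is, at its
$10^{-2}$ cap) is necessarily one-sided.

`iterativeFixing()` is the calibration loop: multistart fit → profile
every free parameter → fix the identifiable ones at their optima (all at
once within an iteration; the order among simultaneously identifiable
parameters is immaterial and left unspecified). If an iteration fixes
nothing, the multistart solutions are filtered by a two-cluster k-means on
their $\chi^2$ values (deterministic extreme-value initial centers; the
lower-mean cluster is kept, everything if the values are degenerate), and
every parameter whose retained sample is unimodal is fixed at its Gaussian
kernel-density mode (normal reference bandwidth). The unimodality rule is
an explicit heuristic for "ending nearly always in the same value range":
at least 80 % of samples within ±0.5 log10 units of the mode, boundary
inclusive. The loop ends when no parameters remain free, after 20
iterations, or when an iteration can fix nothing — "stalled", a reported
(not raised) terminal state. Every fixing is recorded in a replayable
ledger.

## Numerical choices, degenerate inputs, limitations

* Integrator failure anywhere in the objective is a penalty, not an abort;
  in `simulateModel()` it is a structured error carrying the condition.
* Zero pool totals make the corresponding activity 0 (no 0/0).
* A single-time-point dataset is integrated over a minimal two-point grid.
* `kdeMode()` of a zero-range sample returns that value; `isUnimodal()`
  and `kdeMode()` require ≥ 5 samples.
* Known degeneracy worth remembering: with stress applied in every fitted
  condition, $k_{aa}$ and the mTORC1 input strength enter the dynamics
  only through their sum; separating them requires no-stress data. The
  recovery experiments therefore target profile-identifiable parameters.
* Limitations: no compartments or volume scaling; no explicit mTOR
  complexes, Rheb, or p38/MK2 dynamics; immunoblot noise is idealized as
  independent log-normal; SBML import covers this package's dialect only.

## Problem sizes used by the shipped experiments

Tests and the acceptance script run at documented desk scale: searches at
25 starts (10 seeds), variant-ordering fits at 4–5 starts over 3–5 seeds,
recovery at 10–50 starts with 3–5 free parameters, toy problems for the
profile-likelihood machinery. These sizes were chosen so the full suite
runs on a laptop in minutes while every qualitative conclusion (candidate
ranking, variant ordering, identifiability classes) is stable across
seeds.
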