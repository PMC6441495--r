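Package: mtorStress
Title: Dynamic Modelling of Stress Signaling to mTORC1
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the PI3K/Akt/TSC/mTORC1-mTORC2
    signaling network under arsenite stress, as a family of five nested model variants
    with mass-action kinetics, conserved protein pools and Boolean-like inhibitor
    semantics (wortmannin, MK-2206). Provides synthetic immunoblot time-course
    generation with replicate-level multiplicative noise and per-replicate
    mean-normalization, a weighted least-squares objective with Latin hypercube
    multistart optimization in log10 parameter space, a systematic stress-input
    search ranked by AIC/AICc/BIC with a 5 percent improvement rule, profile
    likelihood identifiability analysis with an iterative parameter-fixing loop,
    and SBML Level 3 model interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
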