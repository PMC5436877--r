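Package: lamellosc
Title: Coupled GTPase-ECM Models of Lamellipod Competition, Polarity and
    Antiphase Oscillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of two competing
    lamellipodia coupled through Rac1/RhoA signaling and extracellular-matrix
    (ECM) contact-area feedback. Implements a family of model variants
    (Lotka-Volterra lamellipod competition with abundant, conserved, or
    effector-delayed GTPase pools; a bistable GTPase toggle with slow ECM
    feedback; and a hybrid conserved-pool relaxation oscillator), together
    with stiff integration, multistart equilibrium enumeration with linear
    stability classification, one-parameter branch sweeps with Hopf, fold and
    transcritical detection, two-parameter regime maps, dynamical phenotype
    classification (polarized, apolar-coexisting, antiphase-oscillatory), and
    mapping of pharmacological or matrix perturbations (ROCK inhibition, PI3K
    upregulation, fibronectin density) to parameter changes and population
    phenotype fractions under cell-to-cell heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
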