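---
title: "Lamellipod competition, GTPase conservation, and antiphase oscillation: the models behind lamellosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lamellipod competition, GTPase conservation, and antiphase oscillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellosc)
```

## The biological question

A migrating cell on a patterned fibronectin substrate typically organizes
its leading edge into one or two lamellipodia. Observed behaviors fall into
three classes: persistent polarization (one lamellipod wins and keeps
winning), apolar behavior (protrusions coexist, with direction wandering
stochastically), and antiphase oscillation (two opposing lamellipodia take
turns growing, half a period apart). `lamellosc` implements a family of
compartment ODE models built to ask which combination of signaling
ingredients can produce all three behaviors and respond to perturbations
the way real cells do.

Each lamellipod is a well-mixed compartment with active Rac (`R_k`,
protrusion-promoting), active Rho (`rho_k`, contraction-promoting via ROCK
and myosin), and a variable `E_k` that stands simultaneously for lamellipod
size, cell–ECM contact area, and the ECM signaling level it generates —
those three quantities rise and fall together, and the model deliberately
does not distinguish them.

## Equations and assumptions

Per lamellipod `k` (with `j` the other one):

$$\frac{dR_k}{dt} = \frac{b_R}{1+\rho_k^n} R_I - \delta R_k, \qquad
  \frac{d\rho_k}{dt} = \frac{b_\rho(E_k)}{1+R_k^n} \rho_I - \rho_k,$$
$$\frac{dE_k}{dt} = \epsilon\,(B_E + A_E E_k) - E_k (L_E E_k + l_c E_j).$$

Assumptions worth stating explicitly:

* **Mutual antagonism acts on activation.** Rac and Rho suppress each
  other's activation rates (GEF-level crosstalk); inactivation rates are
  constant. `n = 1` gives a monostable pair, `n = 3` the classic bistable
  toggle.
* **The inactive pools are shared.** Both lamellipodia draw on the same
  inactive Rac and Rho. Abundant-pool variants fix `R_I = rho_I = 1`
  (the constant is absorbed into `b_R`, `b_rho` by the nondimensional
  scaling); conserved variants integrate `R_I`, `rho_I` as explicit state
  variables with `R_1+R_2+R_I = R_T` and `rho_1+rho_2+rho_I = rho_T`.
  We integrate the pools explicitly — eight equations instead of six —
  precisely so that conservation is a *testable invariant* of the solver
  output rather than an identity imposed by substitution.
* **ECM signaling feeds Rho.** `b_rho(E)` rises with contact area: linearly
  (`k_E + gamma_E E`) in the Model 1 family, and as a saturating Hill term
  (`k_E + gamma_E E^3/(E0^3+E^3)`) in Models 2/3. An optional extension
  (`ecm_to_rac`) multiplies Rac activation by a matching saturating factor
  `1 + gamma_ER E^3/(E0^3+E^3)`; we chose the multiplicative form so the
  extension scales the existing activation rather than bypassing the Rho
  inhibition.
* **Lamellipodia compete.** The quadratic `E` terms are a Lotka–Volterra
  species-competition model: `A_E` self-amplified growth, `L_E`
  self-limitation, `l_c` direct cross-inhibition (membrane tension, shared
  cytoskeletal resources). In the Model 1 family protrusion is
  self-amplifying (`A_E = k_R + gamma_R * source_R`, `B_E = 0`, linear in
  the Rac source) and the ECM pair alone is bistable; in Models 2/3
  protrusion is basal (`B_E = k_R + gamma_R * Hill(R_k)`, `A_E = 0`) and
  the ECM pair is monostable.
* **Timescale placement.** We multiply only the protrusion terms by
  `eps`, exactly as in the dimensionless master form above. An alternative
  reading scales contraction and competition as well; under that reading
  `eps` is a pure time rescaling of the `E` equation, under ours it also
  sets the equilibrium scale `E* = eps A_E/L_E`. The regime *boundaries* of
  the competition submodel are unaffected (the invasion eigenvalues scale
  by `eps > 0` overall), which is why we committed to the literal form.
* **Model 1c effectors.** The effector intermediates are first-order
  trackers `dw_k/dt = eps2 (R_k - w_k)`, `dc_k/dt = eps2 (rho_k - c_k)`,
  substituted for `R_k`, `rho_k` only inside `A_E` and `L_E`. This is the
  simplest dynamics whose fast-effector limit (`eps2` large) collapses to
  Model 1b — the quasi-steady-state property the variant exists to probe.

## What each variant shows

The isolated competition submodel ([`ecm_submodel()`]) has four regimes,
classified in closed form by [`lv_regime()`] from the invasion eigenvalues
`eps A_Ej - l_c (eps A_Ek / L_Ek)` of its two exclusion states: bistable
polarity (I), lamellipod 1 or 2 always wins (II/III), and coexistence
(IV). Coexistence is the model's reading of the apolar/"random" phenotype;
the stochastic wandering of real apolar cells is outside scope.

* **M1A (abundant pools).** Polarity comes from regime I/II/III, and GTPase
  feedback should in principle cycle the system between II and III. With
  the shipped calibration at the realistic timescale `eps = 1` it never
  does: for weak contraction feedback (max `L_E < l_c`) the system cannot
  leave the bistable regime and stays polarized; for strong feedback it
  crosses into regime IV, where coexistence is stable, and de-polarizes.
  (At strongly accelerated ECM dynamics, `eps = 5`, a narrow oscillatory
  band does exist near the boundary between those failure modes — the
  variant is not mathematically incapable of oscillating, it fails at
  biologically sensible timescales; the bundle pins `eps = 1`.)
* **M1B (conserved pools).** Conservation bounds
  `L_E(rho_1) + L_E(rho_2) <= 2 k_rho + gamma_rho rho_T`
  ([`accessible_lv_region()`]); the shipped bundle keeps that bound below
  `2 l_c`, so regime IV is unreachable while each `L_E` can individually
  exceed `l_c`. Relaxation oscillations then occur over a wide range — but
  only when ECM dynamics are *faster* than GTPase dynamics (`eps > 1`; the
  bundle oscillates at `eps = 5` and polarizes for `eps <= 3`). Since
  GTPase turnover (seconds) is actually much faster than shape change
  (minutes), this variant is rejected on timescale grounds.
* **M1C (effectors).** Interposes slower effectors so the GTPases
  themselves can be fast; trajectories converge to M1B's as `eps2` grows
  (sup-norm on `E_1` shrinking monotonically under tenfold steps — the
  package's QSSA test). The slowness requirement merely moves to the
  effectors, which is no more plausible.
* **M2 (bistable toggle, abundant pools).** The toggle provides
  bistability; slow ECM feedback (`eps = 0.1`) cycles `b_rho(E)` across
  the toggle's fold-bounded bistable window (`b_rho` in about
  `[1.8, 5.95]` at the bundle's `b_R = 2.5`), giving antiphase oscillation
  through the `l_c` coupling. Its failure is physiological: reducing
  `gamma_rho` (ROCK inhibition) halts the oscillation in a *non-polar*
  stationary state, whereas real ROCK-inhibited cells polarize.
* **M3 (hybrid).** Toggle kinetics plus conserved pools. The pools couple
  the lamellipodia globally: a 4-variable conserved GTPase system that is
  bistable in the *polarity* sense (mirror-image asymmetric states). Slow
  ECM feedback flips it, producing antiphase oscillation; weaker feedback
  leaves it polarized; and all five perturbation directions come out
  right.

## Calibration of the shipped bundles

No kinetic rates are measured; the calibration recipe is structural. For
the hybrid bundle we: (1) fixed the anchor constants `n = 3`,
`delta = 1`, `R_T = rho_T = 2`, Hill IC50s `R0 = rho0 = 1`, `l_c = 0`;
(2) located, for candidate `b_R`, the `b_rho` window in which the conserved
two-lamellipod GTPase system has stable mirror-polarized states; (3) chose
`k_E`, `gamma_E`, `E0` so that `b_rho(E)` sits inside that window at the
polarized ECM levels and traverses its edge when feedback strengthens; and
(4) searched the remaining free parameters (`b_R`, `k_E`, `gamma_E`, `E0`,
`k_R`, `k_rho`, `eps`) for the reference regime layout: a stable polarized
state at `(gamma_R, gamma_rho) = (0.2, 0.2)` and antiphase oscillation at
`(0.3, 0.4)`, with the boundary moving monotonically under each of the five
perturbation sweeps. The result —

```{r, eval = FALSE}
bundle_model("fig5_hybrid")$params
```

`b_R = 5.4`, `k_E = 4.5`, `gamma_E = 2`, `E0 = 0.32`, `k_R = 0.05`,
`k_rho = 0.075`, `eps = 0.1` — oscillates with period ≈ 128 (in units of
the Rho inactivation time) and phase offset 0.50, and direct lamellipod
coupling `l_c = 0.1` enlarges the oscillatory region relative to
`l_c = 0`, i.e. the mechanical coupling is dispensable but
oscillation-promoting. Equivalent reasoning produced the other bundles;
every bundle's documented behavior is enforced by the test suite, not just
by this description.

## Numerical choices

* **Integration.** Backward-differentiation (deSolve's `bdf`) by default,
  tolerances `1e-8`/`1e-10`, with an implicit Runge–Kutta (`radau`)
  fallback: relaxation cycles have sharp flips, and trajectories that are
  absorbed onto an exclusion face `E_k = 0` defeat lsoda's step
  controller. Output grids are uniform and decoupled from internal steps.
  A negative undershoot beyond `-abs_tol` triggers one retry at 100-fold
  tighter tolerances (the positive orthant is analytically invariant).
* **Equilibria.** Multistart damped Newton from a seeded Latin hypercube
  plus the `E_k = 0` faces and an origin-adjacent point; residual below
  `1e-9`; duplicates merged at `1e-5` (infinity norm). Conserved variants
  are analyzed in pool-eliminated coordinates so the conservation law's
  structural zero eigenvalue does not block stability classification;
  reported eigenvalue counts are those of the reduced system. Stability
  calls use a `1e-8` hyperbolicity band.
* **Continuation.** Natural-parameter sweeping with reseeding (the
  systems are low-dimensional; pseudo-arclength would be overkill). Branch
  identity is nearest-neighbour matching that never links equilibria on
  different boundary faces — this keeps exclusion branches intact through
  transcritical crossings. Eigenvalue sign changes are bisected to `1e-6`
  in the parameter; a real-eigenvalue change inside a persisting branch is
  transcritical-grade, a complex pair is a Hopf, and a branch endpoint
  with a near-zero real eigenvalue is a fold unless another branch passes
  through it (then it is the transcritical seen from the other side).
* **Classification.** The first half of every trajectory is discarded as
  transient. A settled endpoint (rhs norm `< 1e-6`) is polarized when the
  polarity index `|E_1-E_2|/(E_1+E_2)` exceeds 0.2, else apolar. Otherwise
  peaks with prominence at least 1% of the signal mean are detected (the
  experimental literature offers no amplitude threshold separating
  oscillation from damped ringing; 1% is our choice, configurable); a
  sustained oscillation needs at least 5 periods, inter-peak CV below
  0.05, and last-to-first cycle amplitude ratio above 0.9; antiphase means
  a phase offset within `[0.35, 0.65]` of a period. `classify_point()`
  runs a `+1%`-`E_1`-biased initial state and its mirror: opposite
  polarized outcomes mean initial conditions choose the direction
  (`BISTABLE_POLAR`).
* **Problem sizes.** The shipped analyses use horizons of 2000–3000 time
  units (more than ten oscillation periods after the transient), 41-point
  regime-map grids, 50-point sweeps, and 48–100-cell populations; all were
  chosen as the smallest sizes at which the reported quantities are stable
  under doubling.

## Population heterogeneity

The experiments report *fractions* of cells per phenotype. The package's
stand-in is deliberately simple and labeled as such in its reports:
independent lognormal multiplicative noise (median 1, default sigma 0.3) on
the three feedback strengths `gamma_R`, `gamma_rho`, `gamma_E`, each
synthetic cell classified at its drawn parameters. Near the oscillatory
boundary this straddling produces coexisting polarized and oscillatory
subpopulations whose fractions shift in the observed directions under ROCK
inhibition and fibronectin increase. Which parameters actually vary across
real cells, and by how much, is unknown; nothing here fits the published
fraction data.

## Limitations

* Two well-mixed compartments: no spatial gradients, no PDE transport, no
  more than two lamellipodia.
* The apolar state is a fixed point here; real "random" cells wander
  because of fluctuations we do not model.
* Linear `b_rho(E)` in the Model 1 family never saturates; at extreme `E`
  this is unphysical but irrelevant in the calibrated regimes.
* Bundle parameters are calibrated to reproduce regime *structure*, not
  fitted to measurements; absolute rates and the oscillation period are
  meaningful only relative to the Rho inactivation time.
* Passing the shipped tests shows the mechanisms behave as designed under
  the generator's idealized conditions (deterministic dynamics, exact
  symmetry between lamellipodia, lognormal heterogeneity); it does not
  validate the models against imaging data.
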