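# lamellosc

Coupled Rac–Rho–ECM models of lamellipod competition, polarity, and
antiphase oscillation in migrating cells.

Melanoma cells migrating on fibronectin-coated micropost arrays show three
lamellipodial phenotypes: persistently polarized cells, apolar ("random")
cells that extend protrusions in changing directions, and oscillatory cells
whose two opposing lamellipodia expand and contract in antiphase.
`lamellosc` implements a family of two-compartment ODE models that explain
these phenotypes from three ingredients: mutually antagonistic Rac1/RhoA
signaling in each lamellipod, competition of the two lamellipodia for
growth, and feedback between lamellipod size (equivalently, cell–ECM contact
area and integrin-mediated ECM signaling) and RhoA activation. The package
is for modelers who want to simulate these circuits, map their regimes, and
connect pharmacological or matrix perturbations to population-level
phenotype shifts.

## The models

Each lamellipod `k = 1, 2` carries active Rac (`R_k`), active Rho
(`rho_k`), and an ECM signaling level `E_k` (all dimensionless; time is in
units of the Rho inactivation time):

    dR_k/dt   = b_R /(1 + rho_k^n) * R_I  - delta * R_k
    drho_k/dt = b_rho(E_k)/(1 + R_k^n) * rho_I - rho_k
    dE_k/dt   = eps*(B_E + A_E*E_k) - E_k*(L_E*E_k + l_c*E_j),  j != k

`b_rho(E)` is the ECM-dependent Rho activation rate; `B_E`/`A_E` are basal
and self-amplifying protrusion, `L_E` is Rho-driven contraction, and `l_c`
couples the lamellipodia directly. Five variants differ in which subsystem
is bistable and whether the GTPase pools are conserved:

| Variant | Kinetics | Pools | Role |
|---|---|---|---|
| `M1A` | linear (n = 1) | abundant | LV competition; fails to oscillate |
| `M1B` | linear (n = 1) | conserved | oscillates only with fast ECM (eps > 1) |
| `M1C` | linear + effectors | conserved | QSSA-reduces to M1B |
| `M2`  | Hill toggle (n = 3) | abundant | oscillates; wrong ROCK response |
| `M3`  | Hill toggle (n = 3) | conserved | hybrid; matches all observations |

The working hybrid model `M3` is a relaxation oscillator: conservation of
the Rac and Rho pools makes the two-lamellipod GTPase system bistable (a
polarized cell pointing either way), and slow ECM feedback drives it across
that bistable range, flipping the polarity periodically.

## Worked example

```r
library(lamellosc)

m <- bundle_model("fig5_hybrid")   # calibrated hybrid model, n = 3,
                                   # delta = 1, R_T = rho_T = 2, l_c = 0
tr <- simulate_model(m, default_init(m), t_end = 2000, n_out = 1500)
classify_trajectory(tr)
#> <phenotype> OSC_ANTIPHASE (polarity index +0.006)
#>   period 127.6, offset 0.506, 11 periods, cv 0.00354
```

The two lamellipodia oscillate half a period out of phase (offset 0.506)
with period ≈ 128 Rho-inactivation times. Weaker feedback polarizes the
cell instead:

```r
m_weak <- set_model_param(set_model_param(m, "gamma_R", 0.2),
                          "gamma_rho", 0.2)
classify_point(m_weak)
#> [1] "BISTABLE_POLAR"
```

(`BISTABLE_POLAR`: both polarity directions are stable; initial conditions
decide.) Perturbations map onto feedback parameters — ROCK inhibition
scales `gamma_rho` down, fibronectin density scales `gamma_E` up — and
population heterogeneity turns regime boundaries into phenotype fractions:

```r
fr <- phenotype_fractions(m, n_cells = 48, seed = 7,
                          t_end = 1800, n_out = 1200)
fraction_summary(fr)
#>  oscillatory    polarized       apolar unclassified
#>   0.62500000   0.35416667   0.02083333   0.00000000

rock <- apply_perturbation(m, "ROCK_INHIBITION", 0.5)
fraction_summary(phenotype_fractions(rock, n_cells = 48, seed = 7,
                                     t_end = 1800, n_out = 1200))["oscillatory"]
#> oscillatory
#>   0.4791667
```

ROCK inhibition lowers the oscillatory fraction (0.625 → 0.479) and raises
the polarized one, matching the experimental direction. `scenario_checks()`
runs all five observation/prediction directions at once and reports the
classifier-estimated Hopf boundary for each.

A thin CLI wraps the same functions:

```sh
lamellosc simulate --config config.json --seed 1 --out out/
```

with JSON configs naming a task (`simulate`, `equilibria`, `sweep`,
`regime-map`, `population`, `scenarios`) and a shipped bundle
(`fig3_lv`, `model1a`, `model1b_osc`, `model1c`, `model2`, `fig5_hybrid`)
or inline parameters.

## Package layout

- `R/` — model definitions (`model_core`, submodels), stiff integration
  (`dynamics`), multistart equilibrium enumeration (`equilibria`), branch
  sweeps and regime maps (`bifurcation`), trajectory classification
  (`phenotype`), perturbation/population analysis (`experiments`), config
  and bundle IO (`cli_io`).
- `inst/extdata/bundles/` — calibrated parameter bundles (JSON).
- `vignettes/lamellipod-dynamics.Rmd` — the methods vignette: model
  assumptions, calibration recipe, classifier thresholds, limitations.
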