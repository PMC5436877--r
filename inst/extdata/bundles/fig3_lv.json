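{
  "name": "fig3_lv",
  "type": "ecm_submodel",
  "description": "Isolated ECM (lamellipod-competition) submodel with frozen coefficients: the classical Lotka-Volterra competition system. A_E1 = A_E2 = l_c = 1; the constrained sweeps move L_E1 while holding L_E1 + L_E2 = K for K in {0.9, 1.5, 3.5} (paths entirely inside Regime I, crossing the bistable band, and crossing through coexistence, respectively). Shipped at the midpoint of the K = 1.5 path.",
  "parameters": {
    "A_E1": 1.0,
    "A_E2": 1.0,
    "L_E1": 0.75,
    "L_E2": 0.75,
    "l_c": 1.0,
    "eps": 1.0
  },
  "paths_K": [0.9, 1.5, 3.5]
}
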