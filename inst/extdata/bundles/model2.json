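{
  "name": "model2",
  "type": "model",
  "variant": "M2",
  "description": "Bistable-GTPase model: abundant pools, toggle-switch kinetics (n = 3) per lamellipod, slow ECM negative feedback, lamellipodia coupled only through the ECM competition term (l_c = 0.1). At b_R = 2.5 the isolated toggle is bistable for b_rho in about [1.8, 5.95]; k_E and gamma_E are calibrated so b_rho(E) traverses that window, giving antiphase oscillation at the default point. Reducing gamma_rho (ROCK inhibition) yields a non-polarized stationary state - the documented failure of this variant.",
  "parameters": {
    "n": 3,
    "delta": 1.0,
    "b_R": 2.5,
    "k_E": 1.2,
    "gamma_E": 14.0,
    "E0": 0.55,
    "k_R": 0.1,
    "gamma_R": 0.5,
    "R0": 1.0,
    "k_rho": 0.1,
    "gamma_rho": 0.5,
    "rho0": 1.0,
    "eps": 0.1,
    "l_c": 0.1
  }
}
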