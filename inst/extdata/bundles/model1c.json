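{
  "name": "model1c",
  "type": "model",
  "variant": "M1C",
  "description": "As model1b_osc but with first-order effector intermediates (w for Rac-driven protrusion, c for Rho-driven contraction) relaying the GTPase feedback onto the ECM terms on timescale eps2. In the eps2 -> infinity limit the effectors track the GTPases instantaneously and the model reduces to the conserved competition model (quasi-steady-state approximation).",
  "parameters": {
    "n": 1,
    "delta": 1.0,
    "b_R": 1.0,
    "k_E": 0.1,
    "gamma_E": 0.4,
    "k_R": 1.0,
    "gamma_R": 0.3,
    "k_rho": 0.1,
    "gamma_rho": 1.5,
    "eps": 5.0,
    "eps2": 1.0,
    "l_c": 1.0,
    "R_T": 2.0,
    "rho_T": 1.0
  }
}
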