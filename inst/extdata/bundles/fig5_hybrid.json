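{
  "name": "fig5_hybrid",
  "type": "model",
  "variant": "M3",
  "description": "Hybrid model: bistable Rac-Rho toggle (Hill n = 3) with conserved GTPase pools (R_T = rho_T = 2) and slow ECM feedback. Kinetic defaults calibrated so that a bistable range of b_rho exists at the chosen b_R and b_rho(E) traverses it when the feedbacks are strong: (gamma_R, gamma_rho) = (0.2, 0.2) gives a stable polarized cell, (0.3, 0.4) gives antiphase lamellipodial oscillation (the shipped default). Direct competition l_c = 0; the conserved pools alone couple the lamellipodia.",
  "parameters": {
    "n": 3,
    "delta": 1.0,
    "b_R": 5.4,
    "k_E": 4.5,
    "gamma_E": 2.0,
    "E0": 0.32,
    "k_R": 0.05,
    "gamma_R": 0.3,
    "R0": 1.0,
    "k_rho": 0.075,
    "gamma_rho": 0.4,
    "rho0": 1.0,
    "eps": 0.1,
    "l_c": 0.0,
    "R_T": 2.0,
    "rho_T": 2.0
  },
  "reference_points": {
    "polarized": {"l_c": 0.0, "gamma_R": 0.2, "gamma_rho": 0.2},
    "oscillatory": {"l_c": 0.0, "gamma_R": 0.3, "gamma_rho": 0.4}
  }
}
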