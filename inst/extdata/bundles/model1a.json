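{
  "name": "model1a",
  "type": "model",
  "variant": "M1A",
  "description": "Lamellipod-competition model with abundant (unlimited) GTPase pools and linear kinetics, at the realistic ECM timescale eps = 1. Across the calibrated gamma_rho sweep (0.1 to 3) this variant shows only its two documented failure modes: for small gamma_rho (max L_E < l_c) the cell stays polarized; for large gamma_rho it crosses into stable coexistence and de-polarizes. No antiphase oscillation occurs.",
  "parameters": {
    "n": 1,
    "delta": 1.0,
    "b_R": 1.0,
    "k_E": 0.1,
    "gamma_E": 0.4,
    "k_R": 1.0,
    "gamma_R": 0.3,
    "k_rho": 0.1,
    "gamma_rho": 1.0,
    "eps": 1.0,
    "l_c": 1.0
  },
  "calibrated_sweep": {"parameter": "gamma_rho", "lo": 0.1, "hi": 3.0}
}
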