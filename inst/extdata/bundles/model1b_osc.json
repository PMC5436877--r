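{
  "name": "model1b_osc",
  "type": "model",
  "variant": "M1B",
  "description": "Lamellipod-competition model with conserved GTPase pools and linear (n = 1, monostable) kinetics. The ECM competition subsystem supplies bistability; slow GTPase feedback through the contraction strength L_E(rho) = k_rho + gamma_rho*rho drives relaxation oscillations. rho_T = 1 keeps the accessible contraction sum 2*k_rho + gamma_rho*rho_T = 1.7 below 2*l_c, so Regime IV (stable coexistence) is unreachable. Oscillates at the shipped eps = 5 (ECM faster than GTPase); oscillations vanish for eps < 1.",
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
    "l_c": 1.0,
    "R_T": 2.0,
    "rho_T": 1.0
  }
}
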