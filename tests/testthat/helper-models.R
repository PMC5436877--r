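# Shared fixtures: models are cheap to build, so construct them fresh from
# the shipped bundles; classification helpers use shortened horizons that
# still cover > 5 oscillation periods after the discarded transient.

hybrid_model <- function(...) {
  m <- bundle_model("fig5_hybrid")
  ov <- list(...)
  for (p in names(ov)) m <- set_model_param(m, p, ov[[p]])
  m
}

classify_fast <- function(model, seed = 0) {
  classify_point(model, seed = seed, t_end = 2000, n_out = 1500)
}

# A deterministic positive state for a given model (valid pools for the
# conserved variants), mildly asymmetric.
random_state <- function(model, scale = 0.6) {
  nm <- state_names(model)
  s <- stats::setNames(stats::runif(length(nm), 0.05, scale), nm)
  if (inherits(model, "lam_model") && model$variant$conserved) {
    p <- model$params
    s["RI"] <- p$R_T - s[["R1"]] - s[["R2"]]
    s["rhoI"] <- p$rho_T - s[["rho1"]] - s[["rho2"]]
  }
  s
}

# Random but valid parameter sets per variant, for property-style tests.
random_params <- function(tag) {
  p <- list(
    n = if (tag %in% c("M2", "M3")) 3 else 1,
    delta = stats::runif(1, 0.5, 2),
    b_R = stats::runif(1, 0.5, 5),
    k_E = stats::runif(1, 0.1, 4),
    gamma_E = stats::runif(1, 0.1, 3),
    k_R = stats::runif(1, 0.05, 1),
    gamma_R = stats::runif(1, 0.05, 1),
    k_rho = stats::runif(1, 0.05, 1),
    gamma_rho = stats::runif(1, 0.05, 1.5),
    eps = stats::runif(1, 0.05, 5),
    l_c = stats::runif(1, 0, 1.5)
  )
  if (tag %in% c("M2", "M3")) {
    p$E0 <- stats::runif(1, 0.1, 1)
    p$R0 <- 1
    p$rho0 <- 1
  }
  if (tag %in% c("M1B", "M1C", "M3")) {
    p$R_T <- stats::runif(1, 1, 3)
    p$rho_T <- stats::runif(1, 1, 3)
  }
  if (tag == "M1C") p$eps2 <- stats::runif(1, 0.2, 5)
  p
}
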