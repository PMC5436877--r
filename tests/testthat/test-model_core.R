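test_that("ECM-dependent Rho activation follows the Hill identities", {
  m <- hybrid_model()  # M2/M3 form: k_E + gamma_E * E^3/(E0^3 + E^3)
  p <- m$params
  expect_equal(rho_activation_input(m, 0), p$k_E)
  expect_equal(rho_activation_input(m, p$E0), p$k_E + p$gamma_E / 2)
  expect_equal(rho_activation_input(m, 1e9), p$k_E + p$gamma_E,
               tolerance = 1e-6)
  # monotone and bounded
  Ek <- seq(0, 10, length.out = 200)
  v <- rho_activation_input(m, Ek)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= p$k_E + p$gamma_E))
  # linear form for the Model 1 family
  m1 <- bundle_model("model1b_osc")
  expect_equal(rho_activation_input(m1, 2.5),
               m1$params$k_E + m1$params$gamma_E * 2.5)
  expect_error(rho_activation_input(m, -0.1), "Ek")
})

test_that("rhs at the origin reduces to the basal rates (M2)", {
  m <- bundle_model("model2")
  p <- m$params
  s <- stats::setNames(rep(0, 6), state_names(m))
  d <- model_rhs(m, s)
  expect_equal(d[["R1"]], p$b_R)       # inactive pools fixed at 1
  expect_equal(d[["rho1"]], p$k_E)
  expect_equal(d[["E1"]], p$eps * p$k_R)
  expect_equal(d[["R2"]], p$b_R)
})

test_that("rhs commutes with lamellipod exchange for every variant", {
  set.seed(11)
  for (tag in c("M1A", "M1B", "M1C", "M2", "M3")) {
    m <- lam_model(tag, random_params(tag))
    for (k in 1:5) {
      s <- random_state(m)
      d <- model_rhs(m, s)
      d_mirror <- model_rhs(m, mirror_state(m, s))
      expect_equal(unname(d_mirror), unname(mirror_state(m, d)),
                   tolerance = 1e-12,
                   info = paste("variant", tag, "draw", k))
    }
  }
})

test_that("explicit pools make the GTPase totals first integrals", {
  set.seed(4)
  for (tag in c("M1B", "M1C", "M3")) {
    m <- lam_model(tag, random_params(tag))
    s <- random_state(m)
    d <- model_rhs(m, s)
    expect_equal(d[["R1"]] + d[["R2"]] + d[["RI"]], 0, tolerance = 1e-12)
    expect_equal(d[["rho1"]] + d[["rho2"]] + d[["rhoI"]], 0,
                 tolerance = 1e-12)
  }
})

test_that("positive orthant is forward-invariant at the boundary", {
  set.seed(21)
  for (tag in c("M1A", "M2", "M3")) {
    m <- lam_model(tag, random_params(tag))
    nm <- state_names(m)
    for (j in seq_along(nm)) {
      s <- random_state(m)
      s[j] <- 0
      if (inherits(m, "lam_model") && m$variant$conserved) {
        # keep pools consistent after zeroing
        s["RI"] <- max(m$params$R_T - s[["R1"]] - s[["R2"]], 0)
        s["rhoI"] <- max(m$params$rho_T - s[["rho1"]] - s[["rho2"]], 0)
        if (s[[j]] != 0) next
      }
      d <- model_rhs(m, s)
      expect_gte(d[[j]], 0)
    }
  }
})

test_that("M1C with effectors slaved to the GTPases matches M1B", {
  # structural QSSA check: at w = R, c = rho the shared components of the
  # M1C rhs coincide with the M1B rhs
  b <- load_bundle("model1c")
  p <- as.list(b$parameters)
  m1c <- lam_model("M1C", p)
  p$eps2 <- NULL
  m1b <- lam_model("M1B", p)
  s_b <- random_state(m1b)
  s_c <- c(s_b, w1 = s_b[["R1"]], c1 = s_b[["rho1"]],
           w2 = s_b[["R2"]], c2 = s_b[["rho2"]])[state_names(m1c)]
  d_c <- model_rhs(m1c, s_c)
  d_b <- model_rhs(m1b, s_b)
  expect_equal(d_c[names(d_b)], d_b, tolerance = 1e-12)
  expect_equal(unname(d_c[c("w1", "c1", "w2", "c2")]), rep(0, 4))
})

test_that("validation reports unused, missing and invalid fields", {
  p2 <- as.list(load_bundle("model2")$parameters)
  rep1 <- validate_params(c(p2, list(R_T = 2)), "M2")
  expect_true(rep1$ok)
  expect_match(rep1$warnings, "R_T")
  expect_true("R_T" %in% rep1$unused)

  p3 <- as.list(load_bundle("fig5_hybrid")$parameters)
  rep2 <- validate_params(p3, model_variant("M3", ecm_to_rac = TRUE))
  expect_false(rep2$ok)
  expect_match(rep2$errors, "gamma_ER", all = FALSE)

  p1a <- as.list(load_bundle("model1a")$parameters)
  expect_true(validate_params(p1a, "M1A")$ok)  # n = 1 is the monostable
  p1a$n <- 0                                   # choice for this family
  expect_false(validate_params(p1a, "M1A")$ok)

  expect_error(model_variant("M2", ecm_to_rac = TRUE), "M3")
  expect_error(lam_model("M3", p3[setdiff(names(p3), "R_T")]), "R_T")
})
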