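test_that("stability labels follow the eigenvalue sign structure", {
  expect_identical(classify_stability(c(-1, -2)), "STABLE_NODE")
  expect_identical(classify_stability(c(-0.1 + 2i, -0.1 - 2i, -1)),
                   "STABLE_FOCUS")
  expect_identical(classify_stability(c(0.1 + 2i, 0.1 - 2i, -1)),
                   "UNSTABLE_FOCUS")
  expect_identical(classify_stability(c(1, -1)), "SADDLE")
  expect_identical(classify_stability(c(1, 2)), "UNSTABLE_NODE")
  expect_identical(classify_stability(c(1e-10, -1)), "NONHYPERBOLIC")
})

test_that("finite-difference Jacobian matches the analytic one", {
  # toggle submodel: dR = b_R/(1+rho^n) - delta R, drho = b_rho/(1+R^n) - rho
  g <- gtpase_submodel(2.3, 1.7, n = 3, delta = 0.8)
  analytic <- function(R, rho) {
    matrix(c(-0.8, -2.3 * 3 * rho^2 / (1 + rho^3)^2,
             -1.7 * 3 * R^2 / (1 + R^3)^2, -1),
           2, 2, byrow = TRUE)
  }
  for (s in list(c(0.5, 0.7), c(1.6, 0.2), c(2, 2))) {
    expect_equal(model_jacobian(g, s), analytic(s[1], s[2]),
                 tolerance = 1e-7)
  }
  # linear case (all crosstalk off via n irrelevant at b = 0)
  g0 <- gtpase_submodel(0, 0, n = 1, delta = 1.5)
  expect_equal(model_jacobian(g0, c(0.3, 0.4)), diag(c(-1.5, -1)),
               tolerance = 1e-7)
})

test_that("Jacobian spectrum is invariant under lamellipod exchange", {
  set.seed(5)
  m <- lam_model("M3", random_params("M3"))
  s <- random_state(m)
  ev <- function(x) {
    sort(Re(eigen(model_jacobian(m, x), only.values = TRUE)$values))
  }
  expect_equal(ev(s), ev(mirror_state(m, s)), tolerance = 1e-6)
})

test_that("LV submodel in the bistable wedge has exactly the two exclusion
          attractors", {
  e <- ecm_submodel(A_E1 = 1, A_E2 = 1, L_E1 = 0.8, L_E2 = 0.8, l_c = 1)
  eqs <- find_equilibria(e, n_starts = 16, seed = 1)
  stable <- Filter(function(q) startsWith(q$stability, "STABLE"), eqs)
  expect_length(stable, 2)
  ex_states <- t(vapply(stable, function(q) q$state, c(E1 = 0, E2 = 0)))
  expect_equal(sort(ex_states[, "E1"]), c(0, 1 / 0.8), tolerance = 1e-7)
  # invasion eigenvalue at each exclusion state is eps*A - l_c*E* < 0 here
  for (q in stable) expect_lt(max(Re(q$eigenvalues)), 0)
})

test_that("toggle equilibrium counts: monostable at n = 1, three states at
          n = 3", {
  for (b in list(c(0.3, 4), c(2, 2), c(30, 0.1))) {
    eqs <- find_equilibria(gtpase_submodel(b[1], b[2], n = 1), n_starts = 24,
                           seed = 0)
    expect_length(Filter(function(q) startsWith(q$stability, "STABLE"), eqs),
                  1)
  }
  eqs3 <- find_equilibria(gtpase_submodel(2, 2, n = 3), n_starts = 24,
                          seed = 0)
  expect_length(eqs3, 3)
  labs <- vapply(eqs3, function(q) q$stability, "")
  expect_equal(sum(startsWith(labs, "STABLE")), 2)
  expect_equal(sum(labs == "SADDLE"), 1)
})

test_that("full-model equilibria are genuine rest points with valid pools", {
  m <- hybrid_model(gamma_R = 0.2, gamma_rho = 0.2)
  eqs <- find_equilibria(m, n_starts = 32, seed = 0)
  expect_gt(length(eqs), 0)
  for (q in eqs) {
    expect_lt(q$residual, 1e-9)
    expect_equal(sum(q$state[c("R1", "R2", "RI")]), m$params$R_T,
                 tolerance = 1e-8)
    full_rhs <- model_rhs(m, q$state)
    expect_lt(max(abs(full_rhs)), 1e-8)
    # reduced eigenvalue count excludes the two conservation directions
    expect_length(q$eigenvalues, 6)
  }
  # the polarized pair exists and is stable at weak feedback
  stable <- Filter(function(q) startsWith(q$stability, "STABLE"), eqs)
  pols <- Filter(function(q) abs(q$state[["E1"]] - q$state[["E2"]]) > 0.05,
                 stable)
  expect_length(pols, 2)
})
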