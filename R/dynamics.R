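#' Integrate a model's ODEs
#'
#' Runs a stiff-capable solver (deSolve's lsoda by default) on any model or
#' submodel and returns the solution on a uniform output grid. The relaxation
#' dynamics of these models have sharp transitions, hence the tight default
#' tolerances. A negative undershoot beyond `-abs_tol` triggers one retry at
#' 100x tighter tolerances before failing.
#'
#' @param model a [lam_model()] or submodel
#' @param init initial state (full coordinates), named or in
#'   [state_names()] order
#' @param t_end final time (dimensionless, units of the Rho inactivation
#'   time), > 0
#' @param n_out number of output points (uniform grid from 0 to `t_end`)
#' @param rel_tol,abs_tol solver tolerances, in (0, 1)
#' @param method deSolve integration method; the default BDF copes with the
#'   sharp relaxation transitions and with trajectories absorbed onto the
#'   `E_k = 0` exclusion faces. On an integrator failure the implicit Runge-
#'   Kutta `radau` is tried before giving up.
#' @return an object of class `lam_trajectory`: list with `times` (length
#'   `n_out`), `states` (`n_out` x d matrix), and `model`
#' @export
simulate_model <- function(model, init, t_end, n_out = 1000,
                           rel_tol = 1e-8, abs_tol = 1e-10,
                           method = "bdf") {
  stopifnot(t_end > 0, n_out >= 2,
            rel_tol > 0, rel_tol < 1, abs_tol > 0, abs_tol < 1)
  nm <- state_names(model)
  y0 <- as.numeric(init)
  if (length(y0) != length(nm)) {
    stop("init has length ", length(y0), ", expected ", length(nm),
         call. = FALSE)
  }
  names(y0) <- nm
  if (any(y0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  times <- seq(0, t_end, length.out = n_out)
  derivs <- function(t, y, parms) {
    list(unname(model_rhs(parms, pmax(y, 0))))
  }
  run <- function(rtol, atol) {
    for (meth in unique(c(method, "radau"))) {
      out <- try(suppressWarnings(
        deSolve::ode(y = y0, times = times, func = derivs, parms = model,
                     method = meth, rtol = rtol, atol = atol)
      ), silent = TRUE)
      if (!inherits(out, "try-error") && nrow(out) == n_out &&
          all(is.finite(out))) {
        return(out)
      }
    }
    t_last <- if (inherits(out, "try-error")) NA_real_ else max(out[, 1])
    stop("integration failed (last valid time ", signif(t_last, 6), ")",
         call. = FALSE)
  }
  out <- run(rel_tol, abs_tol)
  states <- out[, -1, drop = FALSE]
  if (min(states) < -abs_tol) {
    out <- run(rel_tol / 100, abs_tol / 100)
    if (nrow(out) < n_out) {
      stop("integration failed at t = ", max(out[, 1]), call. = FALSE)
    }
    states <- out[, -1, drop = FALSE]
    if (min(states) < -abs_tol) {
      stop("state left the positive orthant beyond tolerance (min = ",
           signif(min(states), 3), ")", call. = FALSE)
    }
  }
  states[states < 0] <- 0
  colnames(states) <- nm
  structure(list(times = times, states = states, model = model),
            class = "lam_trajectory")
}

#' @export
print.lam_trajectory <- function(x, ...) {
  cat("<lam_trajectory> ", length(x$times), " points, t in [",
      x$times[1], ", ", x$times[length(x$times)], "], variables: ",
      paste(colnames(x$states), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.lam_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' Column order: time, then the state variables in integration order; full
#' float precision.
#' @param traj a `lam_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(format(as.data.frame(traj), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mass-conservation error along a trajectory
#'
#' For conserved variants integrated with explicit pools, the totals
#' `R1 + R2 + RI` and `rho1 + rho2 + rhoI` are first integrals; this reports
#' the largest deviation of each from its nominal total.
#'
#' @param traj a `lam_trajectory` of a conserved-variant model
#' @return named numeric vector `c(R = ., rho = .)` of maximum absolute
#'   deviations from `R_T`, `rho_T`
#' @export
conservation_error <- function(traj) {
  model <- traj$model
  if (!inherits(model, "lam_model") || !model$variant$conserved) {
    stop("conservation_error requires a conserved-pool variant (M1B/M1C/M3)",
         call. = FALSE)
  }
  S <- traj$states
  totR <- S[, "R1"] + S[, "R2"] + S[, "RI"]
  totrho <- S[, "rho1"] + S[, "rho2"] + S[, "rhoI"]
  c(R = max(abs(totR - model$params$R_T)),
    rho = max(abs(totrho - model$params$rho_T)))
}

#' Default initial condition for phenotype scans
#'
#' A symmetric rest-like state with a small asymmetric perturbation on the
#' ECM components (+`bias` on E1, -`bias` on E2, optionally jittered by
#' `seed`), so that the polarity direction is decided by the dynamics rather
#' than by a large imposed bias. For conserved variants the GTPase mass starts
#' half-active, split equally between the lamellipodia.
#'
#' @param model a [lam_model()] or submodel
#' @param bias relative ECM asymmetry (default 1\%)
#' @param E_base baseline ECM level
#' @param seed optional integer; adds a reproducible uniform jitter of up to
#'   `bias/2` on the ECM components
#' @param mirror logical; swap the lamellipod bias (for paired runs)
#' @return named initial state vector (full coordinates)
#' @export
default_init <- function(model, bias = 0.01, E_base = 1, seed = NULL,
                         mirror = FALSE) {
  nm <- state_names(model)
  jit <- c(0, 0)
  if (!is.null(seed)) {
    jit <- with_local_seed(seed, (stats::runif(2) - 0.5) * bias)
  }
  E1 <- E_base * (1 + bias + jit[1])
  E2 <- E_base * (1 - bias + jit[2])
  if (mirror) { tmp <- E1; E1 <- E2; E2 <- tmp }
  if (inherits(model, "ecm_submodel")) {
    return(c(E1 = E1, E2 = E2))
  }
  if (inherits(model, "gtpase_submodel")) {
    return(c(R = 0.5, rho = 0.5))
  }
  p <- model$params
  if (model$variant$conserved) {
    R0 <- p$R_T / 4; rho0 <- p$rho_T / 4
  } else {
    R0 <- 0.5; rho0 <- 0.5
  }
  s <- c(R1 = R0, rho1 = rho0, E1 = E1, R2 = R0, rho2 = rho0, E2 = E2)
  if (model$variant$conserved) {
    s <- c(s, RI = p$R_T / 2, rhoI = p$rho_T / 2)
  }
  if (model$variant$tag == "M1C") {
    s <- c(s, w1 = R0, c1 = rho0, w2 = R0, c2 = rho0)
  }
  s[nm]
}
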