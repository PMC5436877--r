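#' Isolated ECM competition submodel
#'
#' The lamellipod-size equations with the GTPase-dependent coefficients frozen
#' to constants, i.e. the classical two-species Lotka-Volterra competition
#' system `dEk = eps * A_Ek * Ek - Ek * (L_Ek * Ek + l_c * Ej)` (basal
#' protrusion `B_E = 0`). State: `E1, E2`.
#'
#' @param A_E1,A_E2 protrusion (growth) strengths, > 0
#' @param L_E1,L_E2 contraction (self-limitation) strengths, > 0
#' @param l_c direct competition strength, >= 0
#' @param eps ECM timescale factor, > 0
#' @return an object of class `ecm_submodel`
#' @export
ecm_submodel <- function(A_E1 = 1, A_E2 = 1, L_E1 = 1, L_E2 = 1,
                         l_c = 1, eps = 1) {
  if (any(c(A_E1, A_E2, L_E1, L_E2, eps) <= 0) || l_c < 0) {
    stop("require A_E*, L_E*, eps > 0 and l_c >= 0", call. = FALSE)
  }
  structure(list(params = list(A_E1 = A_E1, A_E2 = A_E2, L_E1 = L_E1,
                               L_E2 = L_E2, l_c = l_c, eps = eps)),
            class = c("ecm_submodel", "lam_submodel"))
}

#' @export
state_names.ecm_submodel <- function(model, reduced = FALSE) c("E1", "E2")

#' @export
model_rhs.ecm_submodel <- function(model, state, reduced = FALSE, ...) {
  p <- model$params
  E1 <- state[[1]]; E2 <- state[[2]]
  c(E1 = p$eps * p$A_E1 * E1 - E1 * (p$L_E1 * E1 + p$l_c * E2),
    E2 = p$eps * p$A_E2 * E2 - E2 * (p$L_E2 * E2 + p$l_c * E1))
}

## vectorized over rows of an m x 2 state matrix (multistart Newton fast path)
rhs_matrix <- function(model, Y) UseMethod("rhs_matrix")

#' @export
rhs_matrix.ecm_submodel <- function(model, Y) {
  p <- model$params
  E1 <- Y[, 1]; E2 <- Y[, 2]
  cbind(p$eps * p$A_E1 * E1 - E1 * (p$L_E1 * E1 + p$l_c * E2),
        p$eps * p$A_E2 * E2 - E2 * (p$L_E2 * E2 + p$l_c * E1))
}

#' Single-compartment Rac-Rho submodel
#'
#' One lamellipod's mutually antagonistic GTPase pair with abundant inactive
#' pools: `dR = b_R/(1 + rho^n) - delta * R`, `drho = b_rho/(1 + R^n) - rho`.
#' Monostable for `n = 1`; the classical bistable toggle switch for `n = 3`
#' and suitable `(b_R, b_rho)`. State: `R, rho`.
#'
#' @param b_R,b_rho basal activation rates, >= 0
#' @param n Hill coefficient of the mutual inhibition, integer >= 1
#' @param delta Rac inactivation rate ratio, > 0
#' @return an object of class `gtpase_submodel`
#' @export
gtpase_submodel <- function(b_R, b_rho, n = 1, delta = 1) {
  if (b_R < 0 || b_rho < 0 || n < 1 || delta <= 0) {
    stop("require b_R, b_rho >= 0, n >= 1, delta > 0", call. = FALSE)
  }
  structure(list(params = list(b_R = b_R, b_rho = b_rho, n = n,
                               delta = delta)),
            class = c("gtpase_submodel", "lam_submodel"))
}

#' @export
state_names.gtpase_submodel <- function(model, reduced = FALSE) c("R", "rho")

#' @export
model_rhs.gtpase_submodel <- function(model, state, reduced = FALSE, ...) {
  p <- model$params
  R <- state[[1]]; rho <- state[[2]]
  c(R = p$b_R / (1 + rho^p$n) - p$delta * R,
    rho = p$b_rho / (1 + R^p$n) - rho)
}

#' @export
rhs_matrix.gtpase_submodel <- function(model, Y) {
  p <- model$params
  R <- Y[, 1]; rho <- Y[, 2]
  cbind(p$b_R / (1 + rho^p$n) - p$delta * R,
        p$b_rho / (1 + R^p$n) - rho)
}

#' @export
print.lam_submodel <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  p <- unlist(x$params)
  cat(paste0(names(p), " = ", signif(p, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Derived ECM submodel of a full model at a given GTPase state
#'
#' Freezes the GTPase-dependent protrusion/contraction coefficients of a full
#' model at the given state, yielding the isolated competition submodel that
#' governs the ECM variables instantaneously. For M2/M3 (where protrusion is
#' basal, `A_E = 0`) there is no LV reduction and an error is raised.
#'
#' @param model a Model 1 family [lam_model()]
#' @param state full model state supplying the feedback sources
#' @return an [ecm_submodel()]
#' @export
frozen_ecm_submodel <- function(model, state) {
  if (!inherits(model, "lam_model") ||
      !model$variant$tag %in% c("M1A", "M1B", "M1C")) {
    stop("LV reduction applies to the Model 1 family only", call. = FALSE)
  }
  p <- model$params
  nm <- state_names(model)
  s <- as.numeric(state); names(s) <- nm
  if (model$variant$tag == "M1C") {
    srcR <- s[c("w1", "w2")]; srcrho <- s[c("c1", "c2")]
  } else {
    srcR <- s[c("R1", "R2")]; srcrho <- s[c("rho1", "rho2")]
  }
  ecm_submodel(A_E1 = p$k_R + p$gamma_R * srcR[[1]],
               A_E2 = p$k_R + p$gamma_R * srcR[[2]],
               L_E1 = p$k_rho + p$gamma_rho * srcrho[[1]],
               L_E2 = p$k_rho + p$gamma_rho * srcrho[[2]],
               l_c = p$l_c, eps = p$eps)
}
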