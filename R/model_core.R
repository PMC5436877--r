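#' @keywords internal
"_PACKAGE"

## Model variant tags. Conservation of the total GTPase pools is a structural
## property of the variant, not a parameter.
.variant_tags <- c("M1A", "M1B", "M1C", "M2", "M3")
.conserved_tags <- c("M1B", "M1C", "M3")

#' Hill function of order 3
#'
#' Saturating response `x^3 / (x0^3 + x^3)` used for all cooperative
#' (toggle-switch grade) crosstalk and feedback terms.
#'
#' @param x input level (>= 0)
#' @param x0 half-saturation constant (IC50, > 0)
#' @return value in `[0, 1)`
#' @keywords internal
hill3 <- function(x, x0) {
  x3 <- x^3
  x3 / (x0^3 + x3)
}

#' Construct a model variant descriptor
#'
#' The five variants differ in which subsystem supplies bistability and which
#' supplies slow negative feedback:
#' \describe{
#'   \item{M1A}{Lotka-Volterra lamellipod competition, linear (Michaelis-Menten
#'     grade, n = 1) GTPase kinetics, abundant GTPase pools.}
#'   \item{M1B}{As M1A but with conserved (limited) Rac and Rho pools shared by
#'     the two lamellipodia.}
#'   \item{M1C}{As M1B with first-order effector intermediates (w, c) relaying
#'     Rac/Rho feedback onto protrusion/contraction on timescale `eps2`.}
#'   \item{M2}{Bistable GTPase toggle (Hill n = 3) per lamellipod, abundant
#'     pools, monostable ECM coupling with slow ECM feedback.}
#'   \item{M3}{Hybrid: bistable toggle kinetics plus conserved pools; optional
#'     ECM-to-Rac feedback (`ecm_to_rac`).}
#' }
#'
#' @param tag one of `"M1A"`, `"M1B"`, `"M1C"`, `"M2"`, `"M3"`
#' @param ecm_to_rac logical; enable the ECM-to-Rac activation extension
#'   (allowed for `"M3"` only)
#' @return an object of class `lam_variant`
#' @export
model_variant <- function(tag, ecm_to_rac = FALSE) {
  tag <- match.arg(toupper(tag), .variant_tags)
  if (isTRUE(ecm_to_rac) && tag != "M3") {
    stop("ecm_to_rac is only available for variant M3", call. = FALSE)
  }
  structure(
    list(tag = tag, ecm_to_rac = isTRUE(ecm_to_rac),
         conserved = tag %in% .conserved_tags),
    class = "lam_variant"
  )
}

#' @export
print.lam_variant <- function(x, ...) {
  cat("<lam_variant>", x$tag,
      if (x$conserved) "(conserved pools)" else "(abundant pools)",
      if (x$ecm_to_rac) "+ ECM->Rac" else "", "\n")
  invisible(x)
}

## Which ParameterSet fields each variant uses.
.param_fields_common <- c("n", "delta", "b_R", "k_E", "gamma_E",
                          "k_R", "gamma_R", "k_rho", "gamma_rho",
                          "eps", "l_c")
param_fields <- function(variant) {
  f <- .param_fields_common
  if (variant$tag %in% c("M2", "M3")) f <- c(f, "E0", "R0", "rho0")
  if (variant$conserved) f <- c(f, "R_T", "rho_T")
  if (variant$tag == "M1C") f <- c(f, "eps2")
  if (variant$ecm_to_rac) f <- c(f, "gamma_ER")
  f
}

## lower bounds (closed) and strictness per field
.param_bounds <- list(
  n = c(1, FALSE), delta = c(0, TRUE), b_R = c(0, FALSE), k_E = c(0, FALSE),
  gamma_E = c(0, FALSE), E0 = c(0, TRUE), k_R = c(0, FALSE),
  gamma_R = c(0, FALSE), R0 = c(0, TRUE), k_rho = c(0, FALSE),
  gamma_rho = c(0, FALSE), rho0 = c(0, TRUE), eps = c(0, TRUE),
  eps2 = c(0, TRUE), l_c = c(0, FALSE), R_T = c(0, TRUE), rho_T = c(0, TRUE),
  gamma_ER = c(0, FALSE)
)

#' Validate a parameter set against a model variant
#'
#' Checks bounds, reports fields that the variant does not use, and lists
#' required fields that are missing. Valid configurations pass silently
#' (empty report).
#'
#' @param params named list of parameters (see [lam_model()])
#' @param variant a [model_variant()] or tag string
#' @return list with character vectors `errors`, `warnings`, `unused`,
#'   `missing`; `ok` is `TRUE` when there are no errors
#' @export
validate_params <- function(params, variant) {
  if (is.character(variant)) variant <- model_variant(variant)
  need <- param_fields(variant)
  have <- names(params)
  missing <- setdiff(need, have)
  unused <- setdiff(intersect(have, names(.param_bounds)), need)
  errors <- character(0)
  warnings <- character(0)
  if (length(missing)) {
    errors <- c(errors, paste0("missing required field(s): ",
                               paste(missing, collapse = ", ")))
  }
  if (length(unused)) {
    warnings <- c(warnings, paste0("field(s) ignored for ", variant$tag, ": ",
                                   paste(unused, collapse = ", ")))
  }
  for (f in intersect(have, need)) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errors <- c(errors, paste0(f, " must be a finite numeric scalar"))
      next
    }
    b <- .param_bounds[[f]]
    if (b[2]) {
      if (v <= b[1]) errors <- c(errors, paste0(f, " must be > ", b[1]))
    } else if (v < b[1]) {
      errors <- c(errors, paste0(f, " must be >= ", b[1]))
    }
  }
  if ("n" %in% have && is.numeric(params$n) &&
      abs(params$n - round(params$n)) > 1e-12) {
    errors <- c(errors, "n must be a positive integer")
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings,
       unused = unused, missing = missing)
}

#' Construct a two-lamellipod GTPase-ECM model
#'
#' Bundles a variant with a validated parameter set. The state vector is
#' ordered `R1, rho1, E1, R2, rho2, E2`, followed by the shared inactive pools
#' `RI, rhoI` for conserved variants and by the effector levels
#' `w1, c1, w2, c2` for M1C.
#'
#' @param variant a [model_variant()] or tag string
#' @param params named list of dimensionless parameters:
#'   \describe{
#'     \item{n}{Hill coefficient of Rac-Rho mutual inhibition (1 = monostable
#'       Michaelis-Menten grade, 3 = bistable toggle).}
#'     \item{delta}{Rac inactivation rate relative to Rho's (time unit).}
#'     \item{b_R}{basal Rac activation rate.}
#'     \item{k_E, gamma_E}{basal and ECM-induced parts of the Rho activation
#'       rate `b_rho(E)`; linear slope for M1*, Hill magnitude (with IC50
#'       `E0`) for M2/M3.}
#'     \item{k_R, gamma_R}{basal and Rac-fed protrusion strength; linear in
#'       the Rac feedback source for M1*, Hill (IC50 `R0`) for M2/M3.}
#'     \item{k_rho, gamma_rho}{basal and Rho-fed contraction strength;
#'       linear for M1*, Hill (IC50 `rho0`) for M2/M3.}
#'     \item{eps}{ECM (protrusion) timescale ratio; > 1 means ECM dynamics
#'       faster than GTPase dynamics.}
#'     \item{eps2}{effector relaxation rate (M1C only).}
#'     \item{l_c}{direct lamellipod competition strength.}
#'     \item{R_T, rho_T}{total Rac/Rho (conserved variants only).}
#'     \item{gamma_ER}{ECM-to-Rac feedback magnitude (M3 with `ecm_to_rac`).}
#'   }
#' @param ecm_to_rac convenience flag forwarded to [model_variant()] when
#'   `variant` is a tag string
#' @return an object of class `lam_model`
#' @export
lam_model <- function(variant, params, ecm_to_rac = FALSE) {
  if (is.character(variant)) variant <- model_variant(variant, ecm_to_rac)
  rep <- validate_params(params, variant)
  if (!rep$ok) {
    stop("invalid parameters for ", variant$tag, ":\n  ",
         paste(rep$errors, collapse = "\n  "), call. = FALSE)
  }
  for (w in rep$warnings) warning(w, call. = FALSE)
  params <- params[param_fields(variant)]
  structure(list(variant = variant, params = params),
            class = "lam_model")
}

#' @export
print.lam_model <- function(x, ...) {
  cat("<lam_model>", x$variant$tag,
      if (x$variant$conserved) "(conserved)" else "(abundant)", "\n")
  p <- unlist(x$params)
  cat(paste0("  ", names(p), " = ", signif(p, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' State variable names of a model
#'
#' @param model a [lam_model()] (or ECM/GTPase submodel)
#' @param reduced drop the inactive pools (conserved variants), which are then
#'   implied by `RI = R_T - R1 - R2` etc.
#' @return character vector of state names in integration order
#' @export
state_names <- function(model, reduced = FALSE) {
  UseMethod("state_names")
}

#' @export
state_names.lam_model <- function(model, reduced = FALSE) {
  nm <- c("R1", "rho1", "E1", "R2", "rho2", "E2")
  if (model$variant$conserved && !reduced) nm <- c(nm, "RI", "rhoI")
  if (model$variant$tag == "M1C") nm <- c(nm, "w1", "c1", "w2", "c2")
  nm
}

#' ECM-dependent Rho activation rate
#'
#' The basal Rho activation rate as modulated by ECM signaling level `Ek`:
#' linear `k_E + gamma_E * Ek` for the Model 1 family, saturating
#' `k_E + gamma_E * Ek^3 / (E0^3 + Ek^3)` for M2/M3.
#'
#' @param model a [lam_model()]
#' @param Ek ECM signaling level(s), >= 0 (vectorized)
#' @return activation rate(s) `b_rho(Ek)`
#' @export
rho_activation_input <- function(model, Ek) {
  if (any(Ek < 0)) stop("Ek must be >= 0", call. = FALSE)
  p <- model$params
  if (model$variant$tag %in% c("M2", "M3")) {
    p$k_E + p$gamma_E * hill3(Ek, p$E0)
  } else {
    p$k_E + p$gamma_E * Ek
  }
}

#' Time derivative of the model state
#'
#' Evaluates the coupled Rac/Rho/ECM kinetics for both lamellipodia. Per
#' lamellipod k (j the other one):
#' `dRk = b_R/(1 + rhok^n) * RI - delta * Rk`,
#' `drhok = b_rho(Ek)/(1 + Rk^n) * rhoI - rhok`,
#' `dEk = eps * (B_E + A_E * Ek) - Ek * (L_E * Ek + l_c * Ej)`,
#' with `A_E` linear in the Rac feedback source and `B_E = 0` for the Model 1
#' family, and `B_E` a Hill function of Rac with `A_E = 0` for M2/M3. The
#' inactive pools are constant (= 1) for abundant variants and explicit state
#' variables for conserved ones; M1C adds effector trackers
#' `dwk = eps2 * (Rk - wk)`, `dck = eps2 * (rhok - ck)` which replace Rk, rhok
#' in the ECM feedback terms.
#'
#' @param model a [lam_model()]
#' @param state named (or ordered per [state_names()]) numeric state vector
#' @param reduced use the pool-eliminated coordinates (conserved variants)
#' @param ... further arguments for methods (`check = FALSE` skips the
#'   nonnegativity domain check, used internally by root polishing)
#' @return named numeric vector of time derivatives
#' @export
model_rhs <- function(model, state, reduced = FALSE, ...) {
  UseMethod("model_rhs")
}

#' @export
model_rhs.lam_model <- function(model, state, reduced = FALSE, check = TRUE,
                                ...) {
  p <- model$params
  tag <- model$variant$tag
  conserved <- model$variant$conserved
  nm <- state_names(model, reduced = reduced)
  if (length(state) != length(nm)) {
    stop("state has length ", length(state), ", expected ", length(nm),
         " for ", tag, if (reduced) " (reduced)", call. = FALSE)
  }
  s <- as.numeric(state)
  names(s) <- nm
  if (check && any(s[c("R1", "rho1", "E1", "R2", "rho2", "E2")] < 0)) {
    stop("negative state component", call. = FALSE)
  }

  R <- s[c("R1", "R2")]; rho <- s[c("rho1", "rho2")]
  E <- s[c("E1", "E2")]
  if (conserved) {
    if (reduced) {
      RI <- p$R_T - sum(R); rhoI <- p$rho_T - sum(rho)
    } else {
      RI <- s[["RI"]]; rhoI <- s[["rhoI"]]
    }
  } else {
    RI <- 1; rhoI <- 1
  }

  ## inline b_rho(E) (domain check already done above when `check`)
  b_rho <- if (tag %in% c("M2", "M3")) {
    p$k_E + p$gamma_E * hill3(E, p$E0)
  } else {
    p$k_E + p$gamma_E * E
  }
  b_R <- p$b_R
  if (model$variant$ecm_to_rac) {
    b_R <- b_R * (1 + p$gamma_ER * hill3(E, p$E0))
  }
  actR <- b_R / (1 + rho^p$n) * RI
  actrho <- b_rho / (1 + R^p$n) * rhoI
  dR <- actR - p$delta * R
  drho <- actrho - rho

  ## ECM feedback sources: effectors for M1C, the GTPases themselves otherwise
  if (tag == "M1C") {
    srcR <- s[c("w1", "w2")]; srcrho <- s[c("c1", "c2")]
  } else {
    srcR <- R; srcrho <- rho
  }
  if (tag %in% c("M2", "M3")) {
    B_E <- p$k_R + p$gamma_R * hill3(R, p$R0)
    A_E <- c(0, 0)
    L_E <- p$k_rho + p$gamma_rho * hill3(rho, p$rho0)
  } else {
    B_E <- c(0, 0)
    A_E <- p$k_R + p$gamma_R * srcR
    L_E <- p$k_rho + p$gamma_rho * srcrho
  }
  dE <- p$eps * (B_E + A_E * E) - E * (L_E * E + p$l_c * rev(E))

  d <- c(dR[1], drho[1], dE[1], dR[2], drho[2], dE[2])
  if (conserved && !reduced) {
    d <- c(d, sum(p$delta * R - actR), sum(rho - actrho))
  }
  if (tag == "M1C") {
    d <- c(d, p$eps2 * (R[1] - srcR[1]), p$eps2 * (rho[1] - srcrho[1]),
           p$eps2 * (R[2] - srcR[2]), p$eps2 * (rho[2] - srcrho[2]))
  }
  names(d) <- nm
  d
}

#' Swap the two lamellipodia of a state vector
#'
#' The models are symmetric under relabeling of lamellipod 1 and 2; this
#' helper applies that relabeling to a state (or derivative) vector.
#'
#' @param model a model object
#' @param state state vector in the model's ordering
#' @return the mirrored state vector
#' @export
mirror_state <- function(model, state) {
  nm <- if (length(state) == length(state_names(model))) {
    state_names(model)
  } else {
    state_names(model, reduced = TRUE)
  }
  s <- as.numeric(state)
  names(s) <- nm
  swap <- nm
  swap <- sub("1$", "#", swap)
  swap <- sub("2$", "1", swap)
  swap <- sub("#$", "2", swap)
  out <- s[match(nm, swap)]
  names(out) <- nm
  out
}

#' Completed full state from reduced coordinates
#'
#' For conserved variants, appends the pool levels implied by the totals.
#' @param model a [lam_model()]
#' @param reduced_state state without pools
#' @return full state vector
#' @keywords internal
full_state <- function(model, reduced_state) {
  nm_red <- state_names(model, reduced = TRUE)
  s <- as.numeric(reduced_state)
  names(s) <- nm_red
  if (!model$variant$conserved) return(s)
  p <- model$params
  out <- c(s[c("R1", "rho1", "E1", "R2", "rho2", "E2")],
           RI = unname(p$R_T - s[["R1"]] - s[["R2"]]),
           rhoI = unname(p$rho_T - s[["rho1"]] - s[["rho2"]]))
  extra <- setdiff(nm_red, c("R1", "rho1", "E1", "R2", "rho2", "E2"))
  out <- c(out, s[extra])
  out[state_names(model)]
}
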