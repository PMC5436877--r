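## Reduced-coordinate right-hand side used by all equilibrium machinery.
## Conserved variants are handled in pool-eliminated coordinates so the
## structurally zero eigenvalue of the conservation laws does not obstruct
## hyperbolicity classification.
reduced_rhs <- function(model, x) {
  unname(model_rhs(model, x, reduced = TRUE, check = FALSE))
}

#' Jacobian matrix of the model right-hand side
#'
#' Central finite differences with relative step `1e-6` and absolute floor
#' `1e-8` per coordinate.
#'
#' @param model a [lam_model()] or submodel
#' @param state state at which to linearize (reduced coordinates when
#'   `reduced = TRUE`)
#' @param reduced linearize the pool-eliminated system (the relevant one for
#'   stability of conserved variants)
#' @return a square matrix, `d[rhs_i]/d[state_j]`
#' @export
model_jacobian <- function(model, state, reduced = FALSE) {
  f <- if (reduced) {
    function(x) reduced_rhs(model, x)
  } else {
    function(x) unname(model_rhs(model, x, check = FALSE))
  }
  x <- as.numeric(state)
  d <- length(x)
  J <- matrix(0, d, d)
  h <- pmax(1e-6 * abs(x), 1e-8)
  for (j in seq_len(d)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]; xm[j] <- x[j] - h[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  J
}

#' Classify linear stability from eigenvalues
#'
#' An equilibrium is hyperbolic-stable when the largest real part is below
#' `-tol`, non-hyperbolic when any real part lies within `tol` of zero, and a
#' focus when a non-real pair carries the leading real part.
#'
#' @param eigenvalues complex (or numeric) eigenvalue vector
#' @param tol hyperbolicity tolerance on real parts
#' @return one of `"STABLE_NODE"`, `"STABLE_FOCUS"`, `"SADDLE"`,
#'   `"UNSTABLE_NODE"`, `"UNSTABLE_FOCUS"`, `"NONHYPERBOLIC"`
#' @export
classify_stability <- function(eigenvalues, tol = 1e-8) {
  stopifnot(length(eigenvalues) > 0)
  re <- Re(eigenvalues)
  im <- Im(eigenvalues)
  if (any(abs(re) <= tol)) return("NONHYPERBOLIC")
  lead <- which(re >= max(re) - tol * max(1, abs(max(re))))
  focus <- any(abs(im[lead]) > tol)
  if (max(re) < 0) {
    if (focus) "STABLE_FOCUS" else "STABLE_NODE"
  } else if (focus) {
    "UNSTABLE_FOCUS"
  } else if (any(re < 0)) {
    "SADDLE"
  } else {
    "UNSTABLE_NODE"
  }
}

## Upper bounds of the multistart sampling box, per coordinate (reduced).
start_box <- function(model) {
  if (inherits(model, "ecm_submodel")) {
    p <- model$params
    return(c(max(2, 2 * p$eps * p$A_E1 / p$L_E1),
             max(2, 2 * p$eps * p$A_E2 / p$L_E2)))
  }
  if (inherits(model, "gtpase_submodel")) {
    p <- model$params
    return(c(max(2, 1.5 * p$b_R / p$delta), max(2, 1.5 * p$b_rho)))
  }
  p <- model$params
  gmax <- max(2, p$R_T %||% 0, p$rho_T %||% 0)
  nm <- state_names(model, reduced = TRUE)
  ub <- rep(gmax, length(nm))
  names(ub) <- nm
  ## E equilibria live at eps * A_E / L_E (M1*) or sqrt(eps * B_E / L_E)
  ## (M2/M3); widen the box so large-eps regimes are still sampled
  Amax <- p$k_R + p$gamma_R * gmax
  Lmin <- max(p$k_rho, 0.05)
  Emax <- if (model$variant$tag %in% c("M2", "M3")) {
    sqrt(p$eps * (p$k_R + p$gamma_R) / Lmin)
  } else {
    p$eps * Amax / Lmin
  }
  ub[c("E1", "E2")] <- max(2, 1.5 * Emax)
  ub
}

## Damped Newton from one start; returns the root or NULL.
newton_root <- function(model, x0, tol = 1e-9, max_iter = 60) {
  x <- as.numeric(x0)
  fx <- tryCatch(reduced_rhs(model, x), error = function(e) NULL)
  if (is.null(fx) || !all(is.finite(fx))) return(NULL)
  for (i in seq_len(max_iter)) {
    nf <- inf_norm(fx)
    if (nf < tol) return(x)
    J <- model_jacobian(model, x, reduced = TRUE)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- tryCatch(reduced_rhs(model, xn), error = function(e) NULL)
      ok <- !is.null(fn) && all(is.finite(fn)) && inf_norm(fn) < nf
      if (ok || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    if (!ok) return(NULL)
    x <- xn; fx <- fn
  }
  if (inf_norm(fx) < tol) x else NULL
}

## Vectorized Newton for 2-D submodels (rows of X0 are starts).
newton2_vec <- function(model, X0, tol = 1e-9, max_iter = 60) {
  X <- X0
  m <- nrow(X)
  done <- rep(FALSE, m)
  for (i in seq_len(max_iter)) {
    Fx <- rhs_matrix(model, X)
    res <- pmax(abs(Fx[, 1]), abs(Fx[, 2]))
    done <- done | (res < tol)
    if (all(done)) break
    h1 <- pmax(1e-6 * abs(X[, 1]), 1e-8)
    h2 <- pmax(1e-6 * abs(X[, 2]), 1e-8)
    Fp1 <- rhs_matrix(model, cbind(X[, 1] + h1, X[, 2]))
    Fm1 <- rhs_matrix(model, cbind(X[, 1] - h1, X[, 2]))
    Fp2 <- rhs_matrix(model, cbind(X[, 1], X[, 2] + h2))
    Fm2 <- rhs_matrix(model, cbind(X[, 1], X[, 2] - h2))
    a <- (Fp1[, 1] - Fm1[, 1]) / (2 * h1)  # dF1/dx1
    b <- (Fp2[, 1] - Fm2[, 1]) / (2 * h2)  # dF1/dx2
    cc <- (Fp1[, 2] - Fm1[, 2]) / (2 * h1) # dF2/dx1
    dd <- (Fp2[, 2] - Fm2[, 2]) / (2 * h2) # dF2/dx2
    det <- a * dd - b * cc
    det[abs(det) < 1e-14] <- NA
    s1 <- (dd * Fx[, 1] - b * Fx[, 2]) / det
    s2 <- (a * Fx[, 2] - cc * Fx[, 1]) / det
    ## cap steps to keep iterates finite in flat regions
    cap <- pmax(abs(X[, 1]), abs(X[, 2]), 1)
    sc <- pmax(abs(s1), abs(s2)) / cap
    shrink <- ifelse(sc > 1, sc, 1)
    upd <- !done & is.finite(s1) & is.finite(s2)
    X[upd, 1] <- X[upd, 1] - s1[upd] / shrink[upd]
    X[upd, 2] <- X[upd, 2] - s2[upd] / shrink[upd]
  }
  Fx <- rhs_matrix(model, X)
  ok <- pmax(abs(Fx[, 1]), abs(Fx[, 2])) < tol &
    is.finite(X[, 1]) & is.finite(X[, 2])
  X[ok, , drop = FALSE]
}

## Multistart sample: LHS interior points + boundary faces + origin-adjacent.
start_points <- function(model, n_starts, seed, extra = NULL) {
  ub <- start_box(model)
  d <- length(ub)
  pts <- with_local_seed(seed, lhs::randomLHS(n_starts, d))
  pts <- sweep(pts, 2, ub, `*`)
  nm <- state_names(model, reduced = TRUE)
  Ecols <- which(nm %in% c("E1", "E2"))
  faces <- NULL
  if (length(Ecols) == 2) {
    n_face <- max(4L, ceiling(n_starts / 4))
    base <- pts[seq_len(min(n_face, nrow(pts))), , drop = FALSE]
    f1 <- base; f1[, Ecols[1]] <- 0
    f2 <- base; f2[, Ecols[2]] <- 0
    f3 <- base; f3[, Ecols] <- 0
    faces <- rbind(f1, f2, f3)
  }
  near0 <- matrix(1e-3, 1, d)
  out <- rbind(pts, faces, near0)
  if (!is.null(extra)) out <- rbind(out, extra)
  colnames(out) <- nm
  out
}

#' Enumerate equilibria and classify their stability
#'
#' Multistart Newton root search over a seeded Latin-hypercube sample of the
#' positive orthant plus the single-lamellipod boundary faces (`E_k = 0`) and
#' an origin-adjacent point. Roots are polished to residual below
#' `residual_tol`, deduplicated at `dedup_tol` (infinity norm), restricted to
#' the closed positive orthant, and sorted by `E1` descending. Conserved
#' variants are analyzed in pool-eliminated coordinates; reported eigenvalues
#' are those of the reduced system.
#'
#' @param model a [lam_model()] or submodel
#' @param n_starts number of interior Latin-hypercube starts (>= 8)
#' @param seed RNG seed for the start sample
#' @param dedup_tol merge radius for duplicate roots
#' @param residual_tol max acceptable infinity norm of the rhs at a root
#' @param extra_starts optional matrix of additional start points (reduced
#'   coordinates), e.g. equilibria carried over from a neighboring parameter
#'   value during continuation
#' @return list of `lam_equilibrium` objects, each with elements `state`
#'   (full coordinates), `reduced_state`, `eigenvalues`, `stability`,
#'   `residual`
#' @export
find_equilibria <- function(model, n_starts = 32, seed = 0, dedup_tol = 1e-5,
                            residual_tol = 1e-9, extra_starts = NULL) {
  stopifnot(n_starts >= 8)
  starts <- start_points(model, n_starts, seed, extra = extra_starts)
  d <- ncol(starts)
  roots <- NULL
  if (d == 2 && inherits(model, "lam_submodel")) {
    roots <- newton2_vec(model, starts, tol = residual_tol)
    if (is.null(roots) || nrow(roots) == 0) {
      ## vectorized pass converged nowhere (extreme parameter corners):
      ## fall back to damped scalar Newton on a subset of starts
      acc <- list()
      for (i in seq_len(min(nrow(starts), 16L))) {
        r <- newton_root(model, starts[i, ], tol = residual_tol)
        if (!is.null(r)) acc[[length(acc) + 1L]] <- r
      }
      roots <- do.call(rbind, acc)
    }
  } else {
    acc <- list()
    for (i in seq_len(nrow(starts))) {
      r <- newton_root(model, starts[i, ], tol = residual_tol)
      if (!is.null(r)) acc[[length(acc) + 1L]] <- r
    }
    roots <- do.call(rbind, acc)
  }
  if (is.null(roots) || nrow(roots) == 0) {
    warning("no equilibrium converged from any start", call. = FALSE)
    return(list())
  }
  ## positive orthant (closed); snap numerically-zero coordinates
  keep <- apply(roots, 1, function(x) all(x > -1e-7))
  roots <- roots[keep, , drop = FALSE]
  if (nrow(roots) == 0) return(list())
  roots[abs(roots) < 1e-9] <- 0
  ## dedup
  uniq <- list()
  for (i in seq_len(nrow(roots))) {
    x <- roots[i, ]
    dup <- FALSE
    for (u in uniq) if (inf_norm(x - u) < dedup_tol) { dup <- TRUE; break }
    if (!dup) uniq[[length(uniq) + 1L]] <- x
  }
  nm <- state_names(model, reduced = TRUE)
  eqs <- lapply(uniq, function(x) {
    names(x) <- nm
    J <- model_jacobian(model, x, reduced = TRUE)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    st <- if (inherits(model, "lam_model")) full_state(model, x) else x
    structure(list(state = st, reduced_state = x,
                   eigenvalues = as.complex(ev),
                   stability = classify_stability(ev),
                   residual = inf_norm(reduced_rhs(model, x))),
              class = "lam_equilibrium")
  })
  key <- if ("E1" %in% nm) "E1" else nm[1]
  ord <- order(-vapply(eqs, function(e) e$reduced_state[[key]], 0))
  eqs[ord]
}

#' @export
print.lam_equilibrium <- function(x, ...) {
  cat("<equilibrium> ", x$stability,
      " | residual ", signif(x$residual, 3), "\n  state: ",
      paste0(names(x$state), " = ", signif(x$state, 5), collapse = ", "),
      "\n  leading eig: ", format(signif(x$eigenvalues[1], 5)), "\n", sep = "")
  invisible(x)
}

#' Count stable equilibria of a model
#'
#' @param model a model or submodel
#' @param ... forwarded to [find_equilibria()]
#' @return integer count of equilibria classified stable
#' @export
count_stable <- function(model, ...) {
  eqs <- find_equilibria(model, ...)
  sum(vapply(eqs, function(e) startsWith(e$stability, "STABLE"), TRUE))
}

#' Serialize equilibria to a report list (JSON-ready)
#' @param eqs list of `lam_equilibrium`
#' @return list of plain lists with state, eigenvalue re/im, stability,
#'   residual
#' @export
equilibria_report <- function(eqs) {
  lapply(eqs, function(e) {
    list(state = as.list(e$state),
         eigenvalues = lapply(e$eigenvalues,
                              function(z) list(re = Re(z), im = Im(z))),
         stability = e$stability,
         residual = e$residual)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
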