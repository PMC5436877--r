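#' Closed-form regime of the isolated ECM competition submodel
#'
#' Classifies the Lotka-Volterra lamellipod competition system from the
#' invasion eigenvalues of its two exclusion equilibria
#' (`E_k* = eps * A_Ek / L_Ek`): lamellipod j can invade the k-dominant state
#' iff `eps * A_Ej - l_c * E_k* > 0`. Neither invading gives bistable
#' polarity (Regime I), both give coexistence (Regime IV), exactly one gives
#' competitive exclusion by the invader (Regimes II/III).
#'
#' @param A_E1,A_E2 protrusion strengths, > 0
#' @param L_E1,L_E2 contraction strengths, > 0
#' @param l_c competition strength, >= 0
#' @param eps ECM timescale factor
#' @param tol invasion eigenvalues within `tol` of zero give `"BOUNDARY"`
#' @return one of `"I_BISTABLE"`, `"II_LAM1_WINS"`, `"III_LAM2_WINS"`,
#'   `"IV_COEXIST"`, `"BOUNDARY"`
#' @export
lv_regime <- function(A_E1, A_E2, L_E1, L_E2, l_c, eps = 1, tol = 1e-12) {
  if (any(c(A_E1, A_E2, L_E1, L_E2) <= 0) || l_c < 0) {
    stop("require A_E*, L_E* > 0 and l_c >= 0", call. = FALSE)
  }
  inv1 <- eps * A_E1 - l_c * eps * A_E2 / L_E2  # 1 invades the 2-wins state
  inv2 <- eps * A_E2 - l_c * eps * A_E1 / L_E1  # 2 invades the 1-wins state
  if (abs(inv1) <= tol || abs(inv2) <= tol) return("BOUNDARY")
  if (inv1 > 0 && inv2 > 0) return("IV_COEXIST")
  if (inv1 < 0 && inv2 < 0) return("I_BISTABLE")
  if (inv1 > 0) "II_LAM1_WINS" else "III_LAM2_WINS"
}

#' Accessible contraction-strength region under Rho conservation
#'
#' With linear contraction `L_E(rho) = k_rho + gamma_rho * rho` and the Rho
#' pool conserved (`rho1 + rho2 <= rho_T`), the sum
#' `L_E(rho1) + L_E(rho2)` cannot exceed `2 k_rho + gamma_rho * rho_T`; part
#' of the competition parameter plane is therefore inaccessible to the
#' conserved Model 1 variant.
#'
#' @param model an M1B (or M1C) [lam_model()]
#' @return list with `max_LE_sum`, the least upper bound on
#'   `L_E(rho1) + L_E(rho2)`
#' @export
accessible_lv_region <- function(model) {
  if (!inherits(model, "lam_model") ||
      !model$variant$tag %in% c("M1B", "M1C")) {
    stop("the conservation restriction applies to M1B/M1C", call. = FALSE)
  }
  p <- model$params
  list(max_LE_sum = 2 * p$k_rho + p$gamma_rho * p$rho_T)
}

#' Replace one parameter of a model, rebuilding it
#'
#' For the ECM submodel the frozen coefficients (`A_E1`, `A_E2`, `L_E1`,
#' `L_E2`, `l_c`, `eps`) are directly settable; `sum_K` supports the derived
#' sweep that moves `L_E1` while holding `L_E1 + L_E2 = K` fixed.
#'
#' @param model a model or submodel
#' @param name parameter name
#' @param value new value
#' @param sum_K if non-`NULL` and `name == "L_E1"`, also sets
#'   `L_E2 = sum_K - value`
#' @return the rebuilt model
#' @export
set_model_param <- function(model, name, value, sum_K = NULL) {
  p <- model$params
  if (!name %in% names(p)) {
    stop("unknown parameter '", name, "' for this model", call. = FALSE)
  }
  p[[name]] <- value
  if (!is.null(sum_K)) {
    if (name != "L_E1") stop("sum_K is defined for L_E1 sweeps", call. = FALSE)
    p$L_E2 <- sum_K - value
  }
  if (inherits(model, "ecm_submodel")) {
    do.call(ecm_submodel, p)
  } else if (inherits(model, "gtpase_submodel")) {
    do.call(gtpase_submodel, p)
  } else {
    lam_model(model$variant, p)
  }
}

## Track one equilibrium to a new parameter value by Newton from its old
## state; NULL when it cannot be continued there (or, with
## `require_orthant`, when the continued root leaves the closed positive
## orthant — used to pin branch endpoints at orthant exits).
track_root <- function(model, name, value, state, sum_K = NULL,
                       match_tol = 0.25, require_orthant = FALSE) {
  m <- set_model_param(model, name, value, sum_K = sum_K)
  r <- newton_root(m, state)
  if (is.null(r)) return(NULL)
  if (inf_norm(r - as.numeric(state)) > match_tol * (1 + inf_norm(state))) {
    return(NULL)  # jumped to a different equilibrium
  }
  if (require_orthant && any(r < -1e-7)) return(NULL)
  list(model = m, state = r)
}

## Zero pattern of a state (which coordinates sit on the boundary); branch
## matching never links equilibria on different boundary faces, so exclusion
## branches keep their identity through transcritical crossings.
zero_pattern <- function(x, tol = 1e-6) paste(as.integer(abs(x) < tol),
                                              collapse = "")

lead_eig <- function(model, state) {
  ev <- eigen(model_jacobian(model, state, reduced = TRUE),
              only.values = TRUE)$values
  ev[order(-Re(ev))][1]
}

#' One-parameter equilibrium branch sweep with bifurcation detection
#'
#' Natural-parameter continuation: at each step the root search is seeded
#' with the previous step's equilibria plus fresh multistarts; equilibria are
#' linked into branches by nearest-neighbour matching. Sign changes of a
#' branch's leading eigenvalue real part are refined by bisection (parameter
#' tolerance `1e-6`) and labeled `HOPF` (complex pair) or `TRANSCRITICAL`
#' (real eigenvalue, stability exchanged where branches cross); a branch that
#' ends inside the sweep range with its leading real eigenvalue approaching
#' zero is refined the same way and labeled `FOLD`.
#'
#' @param model base model (any variant or submodel)
#' @param name swept parameter (a parameter-set field, or a frozen ECM
#'   coefficient for the submodel)
#' @param lo,hi sweep range (`lo < hi`)
#' @param n_steps number of sweep points (>= 50)
#' @param sum_K see [set_model_param()] (the constrained `L_E1` sweep)
#' @param n_starts,seed,dedup_tol forwarded to [find_equilibria()]
#' @return object of class `lam_sweep`: list with `branches` (data frame:
#'   `param`, `branch`, reduced state columns, `lead_re`, `lead_im`,
#'   `stability`) and `points` (list of bifurcation points with `kind`,
#'   `parameter_name`, `parameter_value`, `state`, `leading_eigenvalues`)
#' @export
sweep_1d <- function(model, name, lo, hi, n_steps = 101, sum_K = NULL,
                     n_starts = 12, seed = 0, dedup_tol = 1e-5) {
  stopifnot(lo < hi, n_steps >= 50)
  values <- seq(lo, hi, length.out = n_steps)
  nm <- state_names(model, reduced = TRUE)
  branches <- list()   # per branch: list(states=list, params=numeric, ...)
  open <- integer(0)   # branch ids continuable at the previous step
  rows <- list()
  for (i in seq_along(values)) {
    m_i <- set_model_param(model, name, values[i], sum_K = sum_K)
    extra <- NULL
    if (length(open)) {
      extra <- do.call(rbind, lapply(branches[open], function(b) {
        b$states[[length(b$states)]]
      }))
    }
    eqs <- suppressWarnings(
      find_equilibria(m_i, n_starts = n_starts, seed = seed,
                      dedup_tol = dedup_tol, extra_starts = extra)
    )
    st_mat <- do.call(rbind, lapply(eqs, function(e) {
      as.numeric(e$reduced_state)
    }))
    assigned <- rep(NA_integer_, length(eqs))
    if (length(open) && length(eqs)) {
      prev <- do.call(rbind, lapply(branches[open], function(b) {
        b$states[[length(b$states)]]
      }))
      D <- as.matrix(stats::dist(rbind(prev, st_mat)))
      D <- D[seq_len(nrow(prev)), nrow(prev) + seq_len(nrow(st_mat)),
             drop = FALSE]
      zp_prev <- apply(prev, 1, zero_pattern)
      zp_new <- apply(st_mat, 1, zero_pattern)
      D[outer(zp_prev, zp_new, `!=`)] <- Inf
      tol_match <- 0.25 * (1 + max(abs(st_mat)))
      repeat {
        if (!any(is.finite(D)) || min(D, na.rm = TRUE) > tol_match) break
        k <- arrayInd(which.min(D), dim(D))
        assigned[k[2]] <- open[k[1]]
        D[k[1], ] <- Inf; D[, k[2]] <- Inf
      }
    }
    new_open <- integer(0)
    for (j in seq_along(eqs)) {
      id <- assigned[j]
      if (is.na(id)) {
        id <- length(branches) + 1L
        branches[[id]] <- list(states = list(), params = numeric(0))
      }
      branches[[id]]$states[[length(branches[[id]]$states) + 1L]] <-
        st_mat[j, ]
      branches[[id]]$params <- c(branches[[id]]$params, values[i])
      lev <- eqs[[j]]$eigenvalues[1]
      rows[[length(rows) + 1L]] <- data.frame(
        param = values[i], branch = id,
        as.list(stats::setNames(st_mat[j, ], nm)),
        lead_re = Re(lev), lead_im = Im(lev),
        stability = eqs[[j]]$stability, check.names = FALSE)
      new_open <- c(new_open, id)
    }
    open <- new_open
  }
  branch_df <- do.call(rbind, rows)
  points <- detect_bifurcations(model, name, values, branch_df, sum_K,
                                dedup_tol)
  structure(list(branches = branch_df, points = points,
                 parameter = name, model = model),
            class = "lam_sweep")
}

## Locate stability changes and branch endpoints; refine by bisection.
detect_bifurcations <- function(model, name, values, branch_df, sum_K,
                                dedup_tol) {
  points <- list()
  if (is.null(branch_df)) return(points)
  nm <- state_names(model, reduced = TRUE)
  add_point <- function(kind, value, state, m_at) {
    ev <- eigen(model_jacobian(m_at, state, reduced = TRUE),
                only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    points[[length(points) + 1L]] <<- list(
      kind = kind, parameter_name = name, parameter_value = value,
      state = stats::setNames(as.numeric(state), nm),
      leading_eigenvalues = ev[seq_len(min(2, length(ev)))])
  }
  for (id in unique(branch_df$branch)) {
    b <- branch_df[branch_df$branch == id, , drop = FALSE]
    b <- b[order(b$param), , drop = FALSE]
    ## stability changes within the branch
    sgn <- sign(b$lead_re)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (k in flips) {
      v_lo <- b$param[k]; v_hi <- b$param[k + 1]
      s <- as.numeric(b[k, nm])
      f_lo <- b$lead_re[k]
      imag_at <- b$lead_im[k] != 0 || b$lead_im[k + 1] != 0
      repeat {
        if (v_hi - v_lo < 1e-6) break
        v_mid <- (v_lo + v_hi) / 2
        tr <- track_root(model, name, v_mid, s, sum_K = sum_K)
        if (is.null(tr)) break
        lev <- lead_eig(tr$model, tr$state)
        if (sign(Re(lev)) == sign(f_lo)) {
          v_lo <- v_mid; s <- tr$state
        } else v_hi <- v_mid
      }
      v_star <- (v_lo + v_hi) / 2
      tr <- track_root(model, name, v_star, s, sum_K = sum_K)
      if (is.null(tr)) next
      add_point(if (imag_at) "HOPF" else "TRANSCRITICAL",
                v_star, tr$state, tr$model)
    }
    ## branch terminates inside the sweep range (at either end): candidate
    ## fold, or an orthant exit through another branch (transcritical)
    refine_end <- function(i_at, i_beyond, s0) {
      v_in <- values[i_at]; v_out <- values[i_beyond]
      s <- s0
      repeat {
        if (abs(v_out - v_in) < 1e-6) break
        v_mid <- (v_in + v_out) / 2
        tr <- track_root(model, name, v_mid, s, sum_K = sum_K,
                         require_orthant = TRUE)
        if (is.null(tr)) v_out <- v_mid else { v_in <- v_mid; s <- tr$state }
      }
      v_star <- (v_in + v_out) / 2
      if (abs(v_star - values[i_beyond]) < 2e-6) return()  # root continues:
      # the branch was re-labeled by the matcher, no bifurcation here
      m_at <- set_model_param(model, name, v_in, sum_K = sum_K)
      lev <- lead_eig(m_at, s)
      if (abs(Re(lev)) < 0.05 && abs(Im(lev)) < 1e-6) {
        ## does another branch pass through this state here?
        others <- branch_df[branch_df$branch != id &
                              abs(branch_df$param - v_star) <=
                              2 * (values[2] - values[1]), , drop = FALSE]
        crossing <- FALSE
        if (nrow(others)) {
          dmin <- min(apply(as.matrix(others[, nm, drop = FALSE]), 1,
                            function(x) inf_norm(x - s)))
          crossing <- dmin < 0.02 * (1 + inf_norm(s))
        }
        add_point(if (crossing) "TRANSCRITICAL" else "FOLD",
                  v_star, s, m_at)
      }
    }
    i_end <- match(b$param[nrow(b)], values)
    if (!is.na(i_end) && i_end < length(values)) {
      refine_end(i_end, i_end + 1L, as.numeric(b[nrow(b), nm]))
    }
    i_start <- match(b$param[1], values)
    if (!is.na(i_start) && i_start > 1) {
      refine_end(i_start, i_start - 1L, as.numeric(b[1, nm]))
    }
  }
  dedup_points(points)
}

## Merge bifurcation points found twice (e.g. a transcritical seen both as a
## stability flip on one branch and as the orthant exit of the crossing
## branch); prefer the more specific transcritical label over fold.
dedup_points <- function(points) {
  if (length(points) < 2) return(points)
  rank <- c(HOPF = 1, TRANSCRITICAL = 2, FOLD = 3)
  ord <- order(vapply(points, function(p) rank[[p$kind]], 0))
  points <- points[ord]
  kept <- list()
  for (p in points) {
    dup <- any(vapply(kept, function(q) {
      abs(q$parameter_value - p$parameter_value) < 1e-3 &&
        inf_norm(q$state - p$state) < 0.05 * (1 + inf_norm(q$state))
    }, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept[order(vapply(kept, function(p) p$parameter_value, 0))]
}

#' @export
print.lam_sweep <- function(x, ...) {
  cat("<lam_sweep> over", x$parameter, "-",
      length(unique(x$branches$branch)), "branches,",
      length(x$points), "bifurcation point(s)\n")
  for (p in x$points) {
    cat(sprintf("  %s at %s = %.6g\n", p$kind, p$parameter_name,
                p$parameter_value))
  }
  invisible(x)
}

#' Two-parameter regime map
#'
#' Labels every point of an `x_param` x `y_param` grid by one of three
#' methods: the closed-form Lotka-Volterra oracle (`ANALYTIC_LV`, isolated
#' ECM submodel only), stable-equilibrium enumeration (`EQUILIBRIUM_COUNT`),
#' or paired-simulation phenotype classification (`SIMULATION_CLASSIFIER`,
#' see [classify_point()]).
#'
#' @param model base model
#' @param x_param,y_param parameter names
#' @param x_values,y_values monotone grids
#' @param method one of `"ANALYTIC_LV"`, `"EQUILIBRIUM_COUNT"`,
#'   `"SIMULATION_CLASSIFIER"`
#' @param seed seed for equilibrium multistarts / classifier initial
#'   conditions
#' @param ... forwarded to [classify_point()] (simulation method) or
#'   [find_equilibria()]
#' @return object of class `lam_regime_map`: grids plus a labels matrix
#'   (`length(x_values)` rows, `length(y_values)` columns)
#' @export
regime_map_2d <- function(model, x_param, y_param, x_values, y_values,
                          method = c("ANALYTIC_LV", "EQUILIBRIUM_COUNT",
                                     "SIMULATION_CLASSIFIER"),
                          seed = 0, ...) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(x_values), !is.unsorted(y_values))
  if (method == "ANALYTIC_LV" && !inherits(model, "ecm_submodel")) {
    stop("ANALYTIC_LV applies to the isolated ECM submodel", call. = FALSE)
  }
  lab <- matrix(NA_character_, length(x_values), length(y_values))
  for (i in seq_along(x_values)) {
    for (j in seq_along(y_values)) {
      m_ij <- set_model_param(set_model_param(model, x_param, x_values[i]),
                              y_param, y_values[j])
      lab[i, j] <- switch(
        method,
        ANALYTIC_LV = do.call(lv_regime, m_ij$params),
        EQUILIBRIUM_COUNT = equilibrium_count_label(m_ij, seed = seed, ...),
        SIMULATION_CLASSIFIER = classify_point(m_ij, seed = seed, ...)
      )
    }
  }
  structure(list(x_param = x_param, y_param = y_param,
                 x_values = x_values, y_values = y_values,
                 labels = lab, method = method),
            class = "lam_regime_map")
}

## Map the stable-equilibrium set to an LV regime label (ECM submodel), or
## to the count for other models.
equilibrium_count_label <- function(model, seed = 0, n_starts = 16, ...) {
  eqs <- suppressWarnings(
    find_equilibria(model, n_starts = n_starts, seed = seed, ...)
  )
  stable <- Filter(function(e) startsWith(e$stability, "STABLE"), eqs)
  if (!inherits(model, "ecm_submodel")) {
    return(as.character(length(stable)))
  }
  thr <- 1e-6
  excl1 <- any(vapply(stable, function(e) {
    e$state[["E1"]] > thr && e$state[["E2"]] <= thr
  }, TRUE))
  excl2 <- any(vapply(stable, function(e) {
    e$state[["E2"]] > thr && e$state[["E1"]] <= thr
  }, TRUE))
  inter <- any(vapply(stable, function(e) all(e$state > thr), TRUE))
  if (inter) return("IV_COEXIST")
  if (excl1 && excl2) return("I_BISTABLE")
  if (excl1) return("II_LAM1_WINS")
  if (excl2) return("III_LAM2_WINS")
  "BOUNDARY"
}

#' @export
print.lam_regime_map <- function(x, ...) {
  cat("<lam_regime_map>", x$method, ":", x$x_param, "x", x$y_param, "grid",
      length(x$x_values), "x", length(x$y_values), "\n")
  print(table(x$labels))
  invisible(x)
}

#' Serialize a regime map to a long data frame (CSV-ready)
#' @param map a `lam_regime_map`
#' @return data frame with columns `x`, `y`, `label`
#' @export
regime_map_df <- function(map) {
  data.frame(x = rep(map$x_values, times = length(map$y_values)),
             y = rep(map$y_values, each = length(map$x_values)),
             label = as.vector(map$labels))
}
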