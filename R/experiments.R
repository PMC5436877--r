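## Perturbation kinds: target parameter and the expected fold direction.
.perturbations <- list(
  ROCK_INHIBITION = list(param = "gamma_rho", dir = "down"),
  PI3K_UP         = list(param = "gamma_R",   dir = "up"),
  FN_UP           = list(param = "gamma_E",   dir = "up"),
  MT_ABLATION     = list(param = "gamma_rho", dir = "up"),
  RAC_INHIBITION  = list(param = "gamma_R",   dir = "down"),
  COUPLING_CHANGE = list(param = "l_c",       dir = "any")
)

#' Map an experimental manipulation onto a model parameter change
#'
#' Each perturbation multiplies one feedback parameter by `fold_change`:
#' ROCK inhibition scales down the Rho-contraction feedback `gamma_rho`
#' (nocodazole microtubule ablation scales it up), PI3K upregulation scales
#' up the Rac-protrusion feedback `gamma_R` (Rac inhibition scales it down),
#' raising fibronectin density scales up the ECM-to-Rho feedback `gamma_E`,
#' and `COUPLING_CHANGE` scales the direct competition strength `l_c`.
#'
#' @param model a [lam_model()]
#' @param kind perturbation name (see above)
#' @param fold_change multiplicative factor, > 0; a direction inconsistent
#'   with the biology of `kind` (e.g. ROCK inhibition with fold > 1) gives a
#'   warning, not an error
#' @return the perturbed model
#' @export
apply_perturbation <- function(model, kind, fold_change) {
  kind <- match.arg(kind, names(.perturbations))
  stopifnot(is.numeric(fold_change), fold_change > 0)
  spec <- .perturbations[[kind]]
  if (!spec$param %in% names(model$params)) {
    stop("model has no parameter ", spec$param, call. = FALSE)
  }
  if ((spec$dir == "down" && fold_change > 1) ||
      (spec$dir == "up" && fold_change < 1)) {
    warning(kind, " normally has fold_change ",
            if (spec$dir == "down") "< 1" else "> 1",
            " (got ", fold_change, ")", call. = FALSE)
  }
  set_model_param(model, spec$param,
                  model$params[[spec$param]] * fold_change)
}

#' Parameter value at which the phenotype switches between oscillatory and
#' non-oscillatory
#'
#' Bisects [classify_point()] outcomes between two parameter values that
#' classify differently (one oscillatory, one not). This is a classifier
#' estimate of the Hopf boundary crossed by the sweep.
#'
#' @param model base model
#' @param name parameter to vary
#' @param lo,hi bracketing values
#' @param tol parameter tolerance of the bisection
#' @param seed,... forwarded to [classify_point()]
#' @return the boundary parameter value, or `NA` if the endpoints do not
#'   bracket a change
#' @export
oscillation_boundary <- function(model, name, lo, hi, tol = 1e-3, seed = 0,
                                 ...) {
  is_osc <- function(v) {
    startsWith(classify_point(set_model_param(model, name, v),
                              seed = seed, ...), "OSC")
  }
  o_lo <- is_osc(lo); o_hi <- is_osc(hi)
  if (o_lo == o_hi) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_osc(mid) == o_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Scenario checks: perturbation directions against observed phenotype shifts
#'
#' For each scenario the mapped feedback parameter is swept across its fold
#' range from the bundle's base point and the resulting phenotypes are
#' required to shift in the direction reported for melanoma cells on
#' fibronectin arrays:
#' \describe{
#'   \item{O1}{ROCK inhibition (lower `gamma_rho`): oscillatory to
#'     polarized.}
#'   \item{O2}{PI3K upregulation / invasiveness (higher `gamma_R`):
#'     oscillation promoted.}
#'   \item{O3}{higher fibronectin (higher `gamma_E`): oscillation promoted.}
#'   \item{P1}{Rac inhibition (lower `gamma_R`): oscillation suppressed in
#'     favor of polarization.}
#'   \item{P2}{microtubule ablation (higher `gamma_rho`): oscillation
#'     promoted.}
#' }
#' The check passes when the oscillatory labels occupy the expected side of
#' the fold sweep (a monotone boundary); the classifier-estimated boundary
#' parameter value is reported when the sweep crosses it.
#'
#' @param model calibrated base model (normally the hybrid bundle, at an
#'   oscillatory base point)
#' @param scenarios subset of `c("O1","O2","O3","P1","P2")`
#' @param folds fold-change grid per scenario (from the base value downward
#'   or upward as appropriate)
#' @param seed,... forwarded to [classify_point()]
#' @return data frame of class `lam_scenarios`: scenario, parameter, fold
#'   range, labels at the extremes, boundary estimate, pass flag
#' @export
scenario_checks <- function(model, scenarios = c("O1", "O2", "O3", "P1", "P2"),
                            folds = c(0.25, 0.5, 0.75, 1),
                            seed = 0, ...) {
  ## low_polar: the oscillation-suppressed end must be a polarized state
  ## ("oscillations are suppressed in favor of persistent polarization")
  scen <- list(
    O1 = list(kind = "ROCK_INHIBITION", low_polar = TRUE),
    O2 = list(kind = "PI3K_UP",         low_polar = FALSE),
    O3 = list(kind = "FN_UP",           low_polar = FALSE),
    P1 = list(kind = "RAC_INHIBITION",  low_polar = TRUE),
    P2 = list(kind = "MT_ABLATION",     low_polar = FALSE)
  )
  scenarios <- match.arg(scenarios, names(scen), several.ok = TRUE)
  folds <- sort(folds)
  rows <- lapply(scenarios, function(sc) {
    kind <- scen[[sc]]$kind
    par <- .perturbations[[kind]]$param
    ## every scenario asserts the same boundary orientation: more feedback
    ## means oscillation. The "down" perturbations (O1, P1) read the sweep
    ## from the base leftward, the "up" ones (O2, O3, P2) read it from a
    ## reduced starting point rightward; the monotone label sequence over
    ## [min(folds), 1] x base checks both at once.
    ff <- sort(folds)
    base <- model$params[[par]]
    labs <- vapply(ff, function(f) {
      classify_point(set_model_param(model, par, base * f),
                     seed = seed, ...)
    }, "")
    osc <- startsWith(labs, "OSC")
    ## oscillation must sit at the high-parameter end and be one-sided
    pass <- osc[length(osc)] && !osc[1] &&
      all(diff(as.integer(osc)) >= 0)
    if (scen[[sc]]$low_polar) {
      pass <- pass && labs[1] %in% c("POLARIZED_1", "POLARIZED_2",
                                     "BISTABLE_POLAR")
    }
    bnd <- if (any(osc) && !all(osc)) {
      lo_f <- max(ff[!osc]); hi_f <- min(ff[osc])
      oscillation_boundary(model, par, base * lo_f, base * hi_f,
                           seed = seed, ...)
    } else NA_real_
    data.frame(scenario = sc, kind = kind, parameter = par,
               fold_min = ff[1], fold_max = ff[length(ff)],
               label_min = labs[1], label_max = labs[length(labs)],
               boundary = bnd, pass = pass)
  })
  structure(do.call(rbind, rows), class = c("lam_scenarios", "data.frame"))
}

#' Phenotype fractions in a heterogeneous cell population
#'
#' Draws `n_cells` parameter sets by independent lognormal multiplicative
#' noise on the selected feedback parameters (median 1, log-sd `sigma`),
#' classifies each synthetic cell with [classify_point()], and aggregates
#' label fractions. Deterministic for a fixed seed; classification failures
#' are counted as `UNCLASSIFIED`, never dropped.
#'
#' @param model base model (the population's typical cell)
#' @param sigma named vector of lognormal sigmas (default 0.3 on `gamma_R`,
#'   `gamma_rho`, `gamma_E`); entries of 0 disable noise on that parameter
#' @param n_cells population size
#' @param seed RNG seed (drives both sampling and classifier initial
#'   conditions)
#' @param ... forwarded to [classify_point()]
#' @return object of class `lam_fractions`: list with `fractions` (named,
#'   sums to 1), `labels` (per cell), `draws` (sampled parameters),
#'   `n_cells`, `seed`
#' @export
phenotype_fractions <- function(model,
                                sigma = c(gamma_R = 0.3, gamma_rho = 0.3,
                                          gamma_E = 0.3),
                                n_cells = 100, seed = 0, ...) {
  stopifnot(n_cells >= 1, all(sigma >= 0))
  sigma <- sigma[sigma > 0]
  bad <- setdiff(names(sigma), names(model$params))
  if (length(bad)) {
    stop("heterogeneity on parameter(s) absent from the model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  draws <- with_local_seed(seed, {
    out <- matrix(1, n_cells, length(sigma),
                  dimnames = list(NULL, names(sigma)))
    for (p in names(sigma)) {
      out[, p] <- stats::rlnorm(n_cells, meanlog = 0, sdlog = sigma[[p]])
    }
    out
  })
  labels <- character(n_cells)
  for (i in seq_len(n_cells)) {
    m_i <- model
    for (p in colnames(draws)) {
      m_i <- set_model_param(m_i, p, model$params[[p]] * draws[i, p])
    }
    labels[i] <- tryCatch(
      classify_point(m_i, seed = seed + i, ...),
      error = function(e) "UNCLASSIFIED"
    )
  }
  all_labels <- c("APOLAR_COEXIST", "POLARIZED_1", "POLARIZED_2",
                  "BISTABLE_POLAR", "OSC_ANTIPHASE", "OSC_OTHER",
                  "UNCLASSIFIED")
  fr <- table(factor(labels, levels = all_labels)) / n_cells
  structure(list(fractions = as.numeric(fr),
                 labels = labels, draws = draws,
                 n_cells = n_cells, seed = seed),
            class = "lam_fractions")
}

#' @export
print.lam_fractions <- function(x, ...) {
  all_labels <- c("APOLAR_COEXIST", "POLARIZED_1", "POLARIZED_2",
                  "BISTABLE_POLAR", "OSC_ANTIPHASE", "OSC_OTHER",
                  "UNCLASSIFIED")
  cat("<phenotype fractions> n =", x$n_cells, ", seed =", x$seed, "\n")
  for (k in seq_along(all_labels)) {
    if (x$fractions[k] > 0) {
      cat(sprintf("  %-15s %.3f\n", all_labels[k], x$fractions[k]))
    }
  }
  invisible(x)
}

#' Aggregate oscillatory / polarized / apolar fractions
#' @param fr a `lam_fractions`
#' @return named numeric: `oscillatory`, `polarized`, `apolar`,
#'   `unclassified`
#' @export
fraction_summary <- function(fr) {
  lv <- c("APOLAR_COEXIST", "POLARIZED_1", "POLARIZED_2", "BISTABLE_POLAR",
          "OSC_ANTIPHASE", "OSC_OTHER", "UNCLASSIFIED")
  f <- stats::setNames(fr$fractions, lv)
  c(oscillatory = unname(f["OSC_ANTIPHASE"] + f["OSC_OTHER"]),
    polarized = unname(f["POLARIZED_1"] + f["POLARIZED_2"] +
                       f["BISTABLE_POLAR"]),
    apolar = unname(f["APOLAR_COEXIST"]),
    unclassified = unname(f["UNCLASSIFIED"]))
}
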