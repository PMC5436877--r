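#' Phenotype classifier thresholds
#'
#' All detection thresholds of the trajectory classifier, with the package
#' defaults. The experimental literature gives no quantitative phenotype
#' criteria, so these are package choices; every one can be overridden.
#'
#' @param polarity_index minimum `|E1 - E2| / (E1 + E2)` for a steady state
#'   to count as polarized
#' @param steady_rhs_norm infinity norm of the rhs at the trajectory end
#'   below which the trajectory counts as settled
#' @param prominence_frac peak prominence threshold, as a fraction of the
#'   signal mean
#' @param min_periods minimum number of full periods observed for any
#'   oscillatory label
#' @param max_period_cv maximum coefficient of variation of inter-peak
#'   intervals for a sustained oscillation
#' @param min_amp_ratio minimum last-to-first peak-to-trough amplitude ratio
#'   (rules out decaying ringing)
#' @param antiphase_window phase-offset window (fractions of a period)
#'   labeled antiphase
#' @return named list of thresholds
#' @export
phenotype_thresholds <- function(polarity_index = 0.2,
                                 steady_rhs_norm = 1e-6,
                                 prominence_frac = 0.01,
                                 min_periods = 5,
                                 max_period_cv = 0.05,
                                 min_amp_ratio = 0.9,
                                 antiphase_window = c(0.35, 0.65)) {
  list(polarity_index = polarity_index, steady_rhs_norm = steady_rhs_norm,
       prominence_frac = prominence_frac, min_periods = min_periods,
       max_period_cv = max_period_cv, min_amp_ratio = min_amp_ratio,
       antiphase_window = antiphase_window)
}

## Local maxima with a prominence criterion: a peak's prominence is its
## height above the higher of the two deepest troughs separating it from
## higher ground (standard topographic definition, linear scan).
find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    higher_l <- which(left > x[i])   # strictly higher ground, so plateau
    higher_r <- which(right > x[i])  # twins do not zero the prominence
    base_l <- min(left[seq(if (length(higher_l)) max(higher_l) else 1,
                           i - 1)])
    base_r <- min(right[seq_len(if (length(higher_r)) min(higher_r)
                                else length(right))])
    (x[i] - max(base_l, base_r)) >= prominence
  }, TRUE)
  cand[keep]
}

#' Oscillation metrics from the two ECM signals
#'
#' Detects peaks on `E1` and `E2` (prominence at least `prominence_frac` of
#' each signal's mean), and summarizes period, peak-to-trough amplitudes,
#' phase offset of `E2` relative to `E1` (fraction of a period in `[0, 1)`),
#' number of observed periods, and the coefficient of variation of the
#' inter-peak intervals.
#'
#' @param times time grid
#' @param E1,E2 ECM signaling series
#' @param prominence_frac peak prominence threshold (fraction of signal mean)
#' @return list with `period`, `amplitude_1`, `amplitude_2`,
#'   `phase_offset_fraction`, `n_periods_observed`, `period_cv`,
#'   `amp_ratio_1` (last/first cycle amplitude), or `NULL` when fewer than
#'   two peaks are found on `E1`
#' @export
oscillation_metrics <- function(times, E1, E2, prominence_frac = 0.01) {
  p1 <- find_peaks(E1, prominence = prominence_frac * max(mean(E1), 1e-12))
  p2 <- find_peaks(E2, prominence = prominence_frac * max(mean(E2), 1e-12))
  if (length(p1) < 2) return(NULL)
  t1 <- times[p1]
  ipi <- diff(t1)
  period <- stats::median(ipi)
  period_cv <- if (length(ipi) > 1) stats::sd(ipi) / mean(ipi) else 0
  ## cycle amplitudes on E1: peak minus following trough
  amp_cycle <- vapply(seq_len(length(p1) - 1), function(k) {
    E1[p1[k]] - min(E1[p1[k]:p1[k + 1]])
  }, 0)
  offs <- if (length(p2)) {
    vapply(times[p2], function(tt) {
      prev <- t1[t1 <= tt]
      if (!length(prev)) NA_real_ else (tt - max(prev)) / period
    }, 0)
  } else NA_real_
  offs <- offs[is.finite(offs)]
  list(period = period,
       amplitude_1 = max(E1) - min(E1),
       amplitude_2 = max(E2) - min(E2),
       phase_offset_fraction = if (length(offs)) stats::median(offs) %% 1
                               else NA_real_,
       n_periods_observed = length(ipi),
       period_cv = period_cv,
       amp_ratio_1 = if (length(amp_cycle) > 1 && amp_cycle[1] > 0) {
         amp_cycle[length(amp_cycle)] / amp_cycle[1]
       } else 1)
}

#' Classify a trajectory into a cell phenotype
#'
#' Discards the first half of the trajectory as transient, then labels the
#' remainder:
#' \itemize{
#'   \item settled (terminal rhs norm below threshold): `POLARIZED_1` /
#'     `POLARIZED_2` when the polarity index `|E1 - E2|/(E1 + E2)` exceeds
#'     its threshold (index of the dominant lamellipod), else
#'     `APOLAR_COEXIST`;
#'   \item sustained oscillation (enough periods, regular, non-decaying):
#'     `OSC_ANTIPHASE` when the `E2`-vs-`E1` phase offset falls in the
#'     antiphase window, else `OSC_OTHER`;
#'   \item anything else `UNCLASSIFIED`.
#' }
#'
#' @param traj a `lam_trajectory` (longer than twice the transient window)
#' @param thresholds see [phenotype_thresholds()]
#' @return list of class `lam_phenotype`: `label`, `polarity_index`,
#'   `metrics` (oscillation metrics or `NULL`), `thresholds`
#' @export
classify_trajectory <- function(traj, thresholds = phenotype_thresholds()) {
  n <- length(traj$times)
  if (n < 8) stop("trajectory too short to classify", call. = FALSE)
  w <- seq(n %/% 2, n)
  S <- traj$states
  E1 <- S[w, "E1"]; E2 <- S[w, "E2"]
  pol_idx <- (mean(E1) - mean(E2)) / max(mean(E1) + mean(E2), 1e-300)
  final_rhs <- inf_norm(model_rhs(traj$model, S[n, ], check = FALSE))
  out <- function(label, metrics = NULL) {
    structure(list(label = label, polarity_index = pol_idx,
                   metrics = metrics, thresholds = thresholds),
              class = "lam_phenotype")
  }
  if (final_rhs < thresholds$steady_rhs_norm) {
    if (abs(pol_idx) > thresholds$polarity_index) {
      return(out(if (pol_idx > 0) "POLARIZED_1" else "POLARIZED_2"))
    }
    return(out("APOLAR_COEXIST"))
  }
  met <- oscillation_metrics(traj$times[w], E1, E2,
                             prominence_frac = thresholds$prominence_frac)
  if (!is.null(met) &&
      met$n_periods_observed >= thresholds$min_periods &&
      met$period_cv < thresholds$max_period_cv &&
      met$amp_ratio_1 > thresholds$min_amp_ratio) {
    off <- met$phase_offset_fraction
    lab <- if (is.finite(off) &&
               off >= thresholds$antiphase_window[1] &&
               off <= thresholds$antiphase_window[2]) {
      "OSC_ANTIPHASE"
    } else "OSC_OTHER"
    return(out(lab, met))
  }
  out("UNCLASSIFIED", met)
}

#' @export
print.lam_phenotype <- function(x, ...) {
  cat("<phenotype>", x$label,
      sprintf("(polarity index %+.3f)", x$polarity_index), "\n")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  period %.4g, offset %.3f, %d periods, cv %.3g\n",
                m$period, m$phase_offset_fraction, m$n_periods_observed,
                m$period_cv))
  }
  invisible(x)
}

#' Classify the phenotype at a parameter point
#'
#' Simulates from a slightly `E1`-biased near-symmetric initial condition and
#' from its mirror image. Two opposite polarized outcomes mean the polarity
#' direction is decided by initial conditions (`BISTABLE_POLAR`); agreement
#' returns the common label; any other disagreement is `UNCLASSIFIED`.
#'
#' @param model a [lam_model()] or submodel
#' @param seed controls the initial-condition jitter
#' @param t_end,n_out simulation length and output resolution; the default
#'   covers well over five periods of every shipped oscillatory bundle after
#'   the transient half is discarded
#' @param thresholds see [phenotype_thresholds()]
#' @param details return the two underlying classifications as attributes
#' @param ... forwarded to [simulate_model()]
#' @return character phenotype label (one of `APOLAR_COEXIST`,
#'   `POLARIZED_1`, `POLARIZED_2`, `BISTABLE_POLAR`, `OSC_ANTIPHASE`,
#'   `OSC_OTHER`, `UNCLASSIFIED`)
#' @export
classify_point <- function(model, seed = 0, t_end = 3000, n_out = 2000,
                           thresholds = phenotype_thresholds(),
                           details = FALSE, ...) {
  cl <- lapply(c(FALSE, TRUE), function(mir) {
    init <- default_init(model, seed = seed, mirror = mir)
    traj <- simulate_model(model, init, t_end = t_end, n_out = n_out, ...)
    classify_trajectory(traj, thresholds = thresholds)
  })
  a <- cl[[1]]$label; b <- cl[[2]]$label
  pols <- c("POLARIZED_1", "POLARIZED_2")
  lab <- if (a %in% pols && b %in% pols && a != b) {
    "BISTABLE_POLAR"
  } else if (a == b) {
    a
  } else {
    "UNCLASSIFIED"
  }
  if (details) {
    attr(lab, "runs") <- cl
  }
  lab
}

#' Relabel a phenotype under the lamellipod mirror symmetry
#' @param label a phenotype label
#' @return the label with `POLARIZED_1` and `POLARIZED_2` exchanged
#' @export
mirror_label <- function(label) {
  switch(label, POLARIZED_1 = "POLARIZED_2", POLARIZED_2 = "POLARIZED_1",
         label)
}

#' Mirror a trajectory (swap the two lamellipodia)
#' @param traj a `lam_trajectory`
#' @return the mirrored trajectory
#' @export
mirror_trajectory <- function(traj) {
  nm <- colnames(traj$states)
  swapped <- sub("#$", "2", sub("2$", "1", sub("1$", "#", nm)))
  S <- traj$states[, match(nm, swapped), drop = FALSE]
  colnames(S) <- nm
  structure(list(times = traj$times, states = S, model = traj$model),
            class = "lam_trajectory")
}
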