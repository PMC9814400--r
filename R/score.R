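#' Composite BLI triage score
#'
#' Combines the three lines of evidence used to triage dose-response
#' data: (i) the presence of a stationary (plateau) phase, (ii) curve
#' shape under a homogeneous 1:1 versus heterogeneous 2:1 model, and
#' (iii) linearity of the observed rates k_obs in concentration. The
#' components are
#' `S_plateau` = fraction of concentrations whose association phase
#' reaches a plateau; `S_shape = exp(-max(0, delta_aicc) / 10)`;
#' `S_kobs` = R squared of the k_obs regression clipped to `[0, 1]`,
#' or 0 if either regression rate is non-positive. The score is
#' `(0.4 S_plateau + 0.3 S_shape + 0.3 S_kobs) * penalty`, with
#' `penalty = 0.5` when the two highest concentrations both lack a
#' plateau, else 1. Clean 1:1 binders score near 1; unspecific,
#' non-saturating binders score well below 0.70, the high/low split.
#'
#' @param plateau_flags logical vector, one per concentration
#' @param conc concentrations matching `plateau_flags`, M
#' @param delta_aicc `AICc(1:1) - AICc(2:1)` from [fit_heterogeneous()]
#' @param r2_kobs R squared from [kobs_analysis()]
#' @param k_on,k_off regression rates from [kobs_analysis()]
#' @param cutoff decision threshold (default 0.70)
#' @return object of class `scorecard` with the components, the
#'   penalty, `score` and `decision` (`"high"`, `"low"` or `"reject"`)
#' @export
score_bli <- function(plateau_flags, conc, delta_aicc, r2_kobs,
                      k_on, k_off, cutoff = 0.70) {
  miss <- !length(plateau_flags) || anyNA(plateau_flags) ||
    is.na(delta_aicc) || is.na(r2_kobs) || is.na(k_on) || is.na(k_off)
  if (miss) {
    return(structure(list(s_plateau = NA, s_shape = NA, s_kobs = NA,
                          penalty = NA, score = NA_real_,
                          decision = "reject", cutoff = cutoff),
                     class = "scorecard"))
  }
  stopifnot(length(plateau_flags) == length(conc))
  s_plateau <- mean(plateau_flags)
  s_shape <- exp(-max(0, delta_aicc) / 10)
  s_kobs <- if (k_on > 0 && k_off > 0) min(max(r2_kobs, 0), 1) else 0
  top2 <- order(conc, decreasing = TRUE)[seq_len(min(2, length(conc)))]
  penalty <- if (!any(plateau_flags[top2])) 0.5 else 1
  score <- (0.4 * s_plateau + 0.3 * s_shape + 0.3 * s_kobs) * penalty
  decision <- if (score >= cutoff) "high" else "low"
  structure(list(s_plateau = s_plateau, s_shape = s_shape,
                 s_kobs = s_kobs, penalty = penalty, score = score,
                 decision = decision, cutoff = cutoff),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat("BLI score card\n")
  cat(sprintf("  S_plateau %.3f  S_shape %.3f  S_kobs %.3f  penalty %s\n",
              x$s_plateau, x$s_shape, x$s_kobs, format(x$penalty)))
  cat(sprintf("  Score_BLI = %.3f -> %s (cutoff %.2f)\n", x$score,
              x$decision, x$cutoff))
  if (!is.null(x$concordance))
    cat(sprintf("  K_D concordance ratio %.2f -> %s\n",
                x$concordance$ratio, x$concordance$flag))
  invisible(x)
}

#' Kinetic versus steady-state affinity concordance
#'
#' Fold discrepancy between the affinity from the global kinetic fit and
#' from the steady-state Langmuir fit:
#' `ratio = max(kd_kin, kd_ss) / min(kd_kin, kd_ss)`. Fragments up to a
#' few-fold discrepancy are retained with a flag; a large discrepancy
#' (for example a 9.5-fold lower kinetic affinity) together with a poor
#' fit warrants rejection.
#'
#' @param kd_kin kinetic affinity, M (> 0)
#' @param kd_ss steady-state affinity, M (> 0)
#' @param flag_ratio ratio above which the fragment is flagged (default 2)
#' @param reject_ratio ratio above which it is rejected (default 5)
#' @return list with `ratio` and `flag` (`"concordant"`,
#'   `"discrepant-retain"` or `"reject"`)
#' @export
kd_concordance <- function(kd_kin, kd_ss, flag_ratio = 2,
                           reject_ratio = 5) {
  if (!is.finite(kd_kin) || !is.finite(kd_ss) || kd_kin <= 0 || kd_ss <= 0)
    stop("both affinities must be positive and finite")
  ratio <- max(kd_kin, kd_ss) / min(kd_kin, kd_ss)
  flag <- if (ratio <= flag_ratio) "concordant"
          else if (ratio <= reject_ratio) "discrepant-retain"
          else "reject"
  list(ratio = ratio, flag = flag)
}

#' Full dose-response analysis of one fragment's dilution series
#'
#' Convenience pipeline: steady-state quantification of every trace,
#' Langmuir steady-state fit, global 1:1 kinetic fit, 2:1 model
#' comparison, k_obs analysis, the composite triage score and the
#' kinetic/steady-state concordance check.
#'
#' @param series list of `sensorgram`s with `conc_M` attributes
#' @param window steady-state window, s (20 s suits the dose-response
#'   schedule)
#' @return a `scorecard` augmented with `kd_ss`, `kd_kin`, `fits`
#'   (the individual fit objects) and `concordance`
#' @export
analyze_dose_series <- function(series, window = 20) {
  ss <- lapply(series, steady_state_response, window = window)
  concs <- vapply(series, function(s) attr(s, "conc_M"), numeric(1))
  req <- vapply(ss, `[[`, numeric(1), "r_eq")
  # one plateau verdict per concentration (all replicates must plateau)
  uc <- sort(unique(concs), decreasing = TRUE)
  plat <- vapply(uc, function(C)
    all(vapply(ss[concs == C], `[[`, logical(1), "plateau")), logical(1))

  fit_ss <- fit_steady_state(concs, req)
  fit_kin <- fit_kinetic_global(series)
  fit_het <- fit_heterogeneous(series, fit_1to1 = fit_kin)
  ko <- kobs_analysis(series)

  card <- score_bli(plat, uc, fit_het$delta_aicc, ko$r_squared,
                    ko$k_on, ko$k_off)
  card$kd_ss <- fit_ss$kd
  card$kd_kin <- fit_kin$kd
  card$concordance <- if (is.finite(fit_ss$kd) && is.finite(fit_kin$kd) &&
                          fit_ss$kd > 0 && fit_kin$kd > 0)
    kd_concordance(fit_kin$kd, fit_ss$kd) else NULL
  card$fits <- list(steady_state = fit_ss, kinetic = fit_kin,
                    heterogeneous = fit_het, kobs = ko)
  card
}
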