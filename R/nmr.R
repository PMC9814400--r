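#' Per-fragment STD effects
#'
#' The STD effect of a signal is `I_diff / I_off * 100` (percent). Only
#' resonances inside the aromatic window are considered; signals with a
#' signal-to-noise ratio `I_diff / noise` below `sn_min` are excluded.
#' The per-fragment mean is the arithmetic mean of the retained signals,
#' and the maximum retained effect is reported. A fragment is confirmed
#' when at least one signal survives the S/N filter.
#'
#' @param signals data frame with columns `fragment_id`, `shift_ppm`,
#'   `i_off`, `i_diff`, `noise`
#' @param aromatic_window lower/upper chemical-shift bounds, ppm
#' @param sn_min signal-to-noise threshold (default 3.0)
#' @return list with `effects` (per-signal table with `std_pct`, `sn`,
#'   `retained`) and `summary` (per-fragment `mean_pct`, `max_pct`,
#'   `n_signals`, `confirmed`)
#' @export
std_effects <- function(signals, aromatic_window = c(6.0, 9.5),
                        sn_min = 3.0) {
  stopifnot(all(c("fragment_id", "shift_ppm", "i_off", "i_diff",
                  "noise") %in% names(signals)))
  if (any(signals$i_off <= 0)) stop("I_off must be > 0")
  sig <- signals[signals$shift_ppm >= aromatic_window[1] &
                 signals$shift_ppm <= aromatic_window[2], , drop = FALSE]
  if (!nrow(sig)) stop("no signals inside the aromatic window")
  sig$std_pct <- sig$i_diff / sig$i_off * 100
  sig$sn <- sig$i_diff / sig$noise
  sig$retained <- sig$sn >= sn_min
  summ <- do.call(rbind, lapply(split(sig, sig$fragment_id), function(d) {
    keep <- d[d$retained, , drop = FALSE]
    data.frame(fragment_id = d$fragment_id[1],
               mean_pct = if (nrow(keep)) mean(keep$std_pct) else NA_real_,
               max_pct = if (nrow(keep)) max(keep$std_pct) else NA_real_,
               n_signals = nrow(keep), confirmed = nrow(keep) > 0)
  }))
  rownames(summ) <- NULL
  list(effects = sig, summary = summ)
}

#' Fit an STD saturation build-up curve
#'
#' Least squares on `STD(t) = STD_max (1 - exp(-k_sat t))`; the initial
#' build-up rate is `STD0 = STD_max * k_sat`, the analytic slope of the
#' model at t = 0, which is the epitope-mapping quantity of interest
#' because it is free of relaxation bias at long saturation times.
#'
#' @param tsat saturation times, s (> 0; >= 4 points)
#' @param std STD effects, percent
#' @return object of class `buildup_fit` with `std_max`, `k_sat`,
#'   `std0`, `se`, `degenerate`
#' @export
fit_buildup <- function(tsat, std) {
  if (is.data.frame(tsat)) { std <- tsat$std_pct; tsat <- tsat$tsat_s }
  stopifnot(length(tsat) == length(std))
  if (length(tsat) < 4) stop("need >= 4 build-up points")
  if (any(tsat <= 0)) stop("saturation times must be > 0")
  if (max(abs(std)) < sqrt(.Machine$double.eps)) {
    return(structure(list(std_max = 0, k_sat = NA_real_, std0 = 0,
                          se = c(std_max = NA, k_sat = NA),
                          degenerate = TRUE),
                     class = "buildup_fit"))
  }
  dat <- data.frame(t = tsat, y = std)
  # multi-start over the saturation rate: build-up curves range from
  # fully saturated to almost linear within the sampled window
  fit <- NULL
  for (k0 in c(2 / min(tsat), 1 / stats::median(tsat), 0.2 / max(tsat))) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ smax * (1 - exp(-k * t)), data = dat,
                        start = list(smax = max(std), k = k0),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(fit) || stats::deviance(f) < stats::deviance(fit)))
      fit <- f
  }
  if (is.null(fit)) {
    return(structure(list(std_max = NA_real_, k_sat = NA_real_,
                          std0 = NA_real_,
                          se = c(std_max = NA, k_sat = NA),
                          degenerate = TRUE),
                     class = "buildup_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(smax = NA, k = NA))
  structure(list(std_max = cf[["smax"]], k_sat = cf[["k"]],
                 std0 = cf[["smax"]] * cf[["k"]],
                 se = c(std_max = unname(se["smax"]),
                        k_sat = unname(se["k"])),
                 degenerate = FALSE, fit = fit, data = dat),
            class = "buildup_fit")
}

#' @export
print.buildup_fit <- function(x, ...) {
  cat("STD build-up fit\n")
  cat(sprintf("  STD_max = %.4g %%  k_sat = %.4g s^-1  STD0 = %.4g %%/s\n",
              x$std_max, x$k_sat, x$std0))
  if (x$degenerate) cat("  ** degenerate (flat or failed)\n")
  invisible(x)
}

#' @export
coef.buildup_fit <- function(object, ...) {
  c(std_max = object$std_max, k_sat = object$k_sat, std0 = object$std0)
}

#' @export
predict.buildup_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else newdata
  object$std_max * (1 - exp(-object$k_sat * t))
}

#' NOE R-factor between experimental and predicted STD0 vectors
#'
#' `R = sqrt( sum((exp_i - calc_i)^2) / sum(exp_i^2) )` over matched
#' protons. Zero iff the vectors are identical; 1 when the prediction is
#' uniformly zero.
#'
#' @param exp_std0 experimental initial rates (matched proton order)
#' @param calc_std0 predicted initial rates
#' @return dimensionless R-factor
#' @export
noe_r_factor <- function(exp_std0, calc_std0) {
  if (length(exp_std0) != length(calc_std0))
    stop("experimental and predicted vectors differ in length")
  denom <- sum(exp_std0^2)
  if (denom <= 0) stop("sum of squared experimental values must be > 0")
  sqrt(sum((exp_std0 - calc_std0)^2) / denom)
}

#' Chemical shift perturbations from paired HSQC peak lists
#'
#' `CSP = sqrt(dH^2 + (w_N * dN)^2)` per residue, with nitrogen weight
#' 0.13. Residues are classified against the CSP distribution over all
#' matched residues: `"strong"` above mean + k2 SD, `"moderate"` above
#' mean + k1 SD, `"none"` otherwise. Residues present in only one state
#' are reported with `NA` CSP and class `"missing"`, never as zero.
#'
#' @param apo,bound data frames with columns `residue`, `dH_ppm`,
#'   `dN_ppm`
#' @param nitrogen_weight scaling of the nitrogen dimension
#' @param sd_multipliers `c(k1, k2)` classification multipliers
#' @return data frame with `residue`, `d_dH`, `d_dN`, `csp`, `class`
#' @export
csp <- function(apo, bound, nitrogen_weight = 0.13,
                sd_multipliers = c(1, 2)) {
  if (anyDuplicated(apo$residue) || anyDuplicated(bound$residue))
    stop("duplicate residue ids")
  all_res <- union(apo$residue, bound$residue)
  ia <- match(all_res, apo$residue)
  ib <- match(all_res, bound$residue)
  d_dH <- bound$dH_ppm[ib] - apo$dH_ppm[ia]
  d_dN <- bound$dN_ppm[ib] - apo$dN_ppm[ia]
  val <- sqrt(d_dH^2 + (nitrogen_weight * d_dN)^2)
  out <- data.frame(residue = all_res, d_dH = d_dH, d_dN = d_dN,
                    csp = val, class = "missing",
                    stringsAsFactors = FALSE)
  ok <- !is.na(val)
  mu <- mean(val[ok]); s <- stats::sd(val[ok])
  if (is.na(s)) s <- 0
  cls <- rep("none", sum(ok))
  cls[val[ok] > mu + sd_multipliers[1] * s] <- "moderate"
  cls[val[ok] > mu + sd_multipliers[2] * s] <- "strong"
  out$class[ok] <- cls
  out
}
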