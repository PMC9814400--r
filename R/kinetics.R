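# Global kinetic fitting of dilution-series sensorgrams.
#
# Parameters are fitted on the log scale (positivity by construction)
# with Levenberg-Marquardt (minpack.lm::nls.lm), three log-spaced starts,
# best residual selected. Residuals are taken over the association and
# dissociation phases of every trace jointly.

# model response for one trace given sites data.frame
trace_model <- function(sites, conc, t_rel, phase, t_assoc) {
  out <- numeric(length(t_rel))
  a <- phase == "association"
  d <- phase == "dissociation"
  if (conc > 0) {
    ma <- matrix(site_assoc(sites, conc, t_rel[a]), ncol = nrow(sites))
    out[a] <- rowSums(ma)
    end <- site_assoc(sites, conc, t_assoc)
    md <- vapply(seq_len(nrow(sites)), function(i)
      end[i] * exp(-sites$k_off[i] * (t_rel[d] - t_assoc)),
      numeric(sum(d)))
    out[d] <- rowSums(matrix(md, ncol = nrow(sites)))
  }
  out
}

prep_traces <- function(series) {
  lapply(series, function(sg) {
    t0 <- assoc_start(sg)
    keep <- sg$phase != "baseline"
    list(conc = attr(sg, "conc_M"),
         t_rel = sg$time_s[keep] - t0,
         phase = sg$phase[keep],
         resp = sg$response_nm[keep],
         t_assoc = dissoc_start(sg) - t0)
  })
}

global_resid <- function(logp, traces, two_site) {
  p <- exp(logp)
  sites <- if (two_site)
    data.frame(k_on = p[c(1, 4)], k_off = p[c(2, 5)], r_max = p[c(3, 6)])
  else data.frame(k_on = p[1], k_off = p[2], r_max = p[3])
  unlist(lapply(traces, function(tr)
    tr$resp - trace_model(sites, tr$conc, tr$t_rel, tr$phase, tr$t_assoc)))
}

# AICc from a residual sum of squares; k counts fitted parameters plus
# the error variance. A small RSS floor keeps the comparison stable when
# both models fit noiseless data to machine precision.
aicc_from_rss <- function(rss, n, k, scale) {
  rss <- rss + 1e-10 * n * scale^2
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

run_global_fit <- function(traces, starts, lower, upper, two_site) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(s), fn = global_resid, traces = traces,
                         two_site = two_site,
                         lower = log(lower), upper = log(upper),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

#' Global 1:1 kinetic fit of a dilution series
#'
#' Fits a single `(k_on, k_off, R_max)` jointly across all sensorgrams
#' of a dilution series, association and dissociation phases
#' simultaneously ("global exponential regression"). The derived
#' affinity is `K_D = k_off / k_on` by construction.
#'
#' @param series list of `sensorgram`s (each with a `conc_M` attribute);
#'   at least 3 concentrations
#' @return object of class `kinetic_fit` with `k_on`, `k_off`, `r_max`,
#'   `kd`, `rss`, `n`, `aicc`, `converged`
#' @export
fit_kinetic_global <- function(series) {
  concs <- vapply(series, function(s) attr(s, "conc_M"), numeric(1))
  if (length(unique(concs)) < 3)
    stop("need >= 3 concentrations for a global kinetic fit")
  traces <- prep_traces(series)
  scale <- max(abs(unlist(lapply(traces, `[[`, "resp"))), 1e-6)
  starts <- lapply(c(1e3, 1e5, 1e7), function(kon)
    c(kon, 10^stats::approx(c(1e3, 1e7), c(-3, -1), kon, rule = 2)$y,
      scale))
  lower <- c(10, 1e-5, 1e-6)
  upper <- c(1e9, 10, 1e3)
  best <- run_global_fit(traces, starts, lower, upper, two_site = FALSE)
  if (is.null(best))
    return(structure(list(k_on = NA, k_off = NA, r_max = NA, kd = NA,
                          rss = NA, n = NA, aicc = NA, converged = FALSE),
                     class = "kinetic_fit"))
  p <- exp(best$par)
  n <- length(unlist(lapply(traces, `[[`, "resp")))
  structure(list(k_on = p[1], k_off = p[2], r_max = p[3],
                 kd = p[2] / p[1], rss = best$deviance, n = n,
                 aicc = aicc_from_rss(best$deviance, n, 4, scale),
                 scale = scale, converged = best$info %in% 1:4),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global 1:1 kinetic fit\n")
  cat(sprintf("  k_on  = %.4g M^-1 s^-1\n  k_off = %.4g s^-1\n", x$k_on,
              x$k_off))
  cat(sprintf("  K_D   = %.4g M\n  R_max = %.4g nm\n", x$kd, x$r_max))
  cat(sprintf("  RSS %.4g over %d points (AICc %.4g)\n", x$rss, x$n,
              x$aicc))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, r_max = object$r_max,
    kd = object$kd)
}

#' Heterogeneous (2:1) kinetic fit and model comparison
#'
#' Fits a sum of two independent 1:1 sites globally across the series
#' and compares it with the 1:1 fit via the small-sample Akaike
#' criterion: `delta_aicc = AICc(1:1) - AICc(2:1)`. Large positive
#' values are evidence of heterogeneous (biphasic) binding; for data
#' generated by a true 1:1 process the second site is degenerate and the
#' parameter penalty makes `delta_aicc <= 0`.
#'
#' @inheritParams fit_kinetic_global
#' @param fit_1to1 optionally, a precomputed [fit_kinetic_global()] result
#' @return object of class `kinetic_fit_2site` with per-site parameter
#'   data frame `sites`, `rss`, `aicc`, `delta_aicc`, and the 1:1 fit
#' @export
fit_heterogeneous <- function(series, fit_1to1 = NULL) {
  if (is.null(fit_1to1)) fit_1to1 <- fit_kinetic_global(series)
  traces <- prep_traces(series)
  scale <- fit_1to1$scale
  if (is.null(scale)) scale <- max(abs(unlist(lapply(traces, `[[`, "resp"))))
  k1 <- if (is.finite(fit_1to1$k_on)) fit_1to1$k_on else 1e4
  k2 <- if (is.finite(fit_1to1$k_off)) fit_1to1$k_off else 0.01
  r1 <- if (is.finite(fit_1to1$r_max)) fit_1to1$r_max else scale
  starts <- list(c(k1, k2, r1 / 2, k1 * 10, k2 * 10, r1 / 2),
                 c(k1, k2, r1 / 2, k1 / 10, k2 / 10, r1 / 2),
                 c(k1 * 3, k2 / 3, r1 / 2, k1 / 3, k2 * 3, r1 / 2))
  lo1 <- c(10, 1e-5, 1e-6); hi1 <- c(1e9, 10, 1e3)
  starts <- lapply(starts, function(s) pmin(pmax(s, rep(lo1, 2) * 1.01),
                                            rep(hi1, 2) * 0.99))
  best <- run_global_fit(traces, starts, rep(lo1, 2), rep(hi1, 2),
                         two_site = TRUE)
  n <- length(unlist(lapply(traces, `[[`, "resp")))
  if (is.null(best))
    return(structure(list(sites = NULL, rss = NA, aicc = NA,
                          delta_aicc = NA, fit_1to1 = fit_1to1,
                          converged = FALSE),
                     class = "kinetic_fit_2site"))
  p <- exp(best$par)
  sites <- data.frame(k_on = p[c(1, 4)], k_off = p[c(2, 5)],
                      r_max = p[c(3, 6)])
  sites$kd <- sites$k_off / sites$k_on
  aicc2 <- aicc_from_rss(best$deviance, n, 7, scale)
  structure(list(sites = sites, rss = best$deviance, aicc = aicc2,
                 delta_aicc = fit_1to1$aicc - aicc2,
                 fit_1to1 = fit_1to1, converged = best$info %in% 1:4),
            class = "kinetic_fit_2site")
}

#' @export
print.kinetic_fit_2site <- function(x, ...) {
  cat("Heterogeneous 2:1 kinetic fit\n")
  print(x$sites, row.names = TRUE)
  cat(sprintf("  delta AICc (1:1 minus 2:1) = %.4g\n", x$delta_aicc))
  invisible(x)
}

#' Observed-rate (k_obs) linearity analysis
#'
#' Fits `R(t) = A (1 - exp(-k_obs t))` to the first 90 percent of each
#' association phase (per concentration), then regresses
#' `k_obs = k_on * C + k_off`. For a 1:1 interaction k_obs is exactly
#' linear in concentration with intercept `k_off`; lack of linearity
#' (low R squared) indicates heterogeneous or unspecific binding. The
#' regression is weighted by the number of replicate estimates behind
#' each concentration; the per-trace fit standard errors are reported
#' but deliberately not used as weights, because for a misspecified 1:1
#' model they grow with the lack of fit and would down-weight exactly
#' the concentrations that carry the heterogeneity signal.
#'
#' @inheritParams fit_kinetic_global
#' @return list with `k_on` (slope), `k_off` (intercept), `r_squared`,
#'   `kobs_table` (per-concentration estimates), `dropped`
#'   (concentrations whose single-exponential fit failed)
#' @export
kobs_analysis <- function(series) {
  concs <- vapply(series, function(s) attr(s, "conc_M"), numeric(1))
  if (length(unique(concs)) < 3) stop("need >= 3 concentrations")
  rows <- list(); dropped <- numeric(0)
  for (C in sort(unique(concs))) {
    idx <- which(concs == C)
    est <- se <- numeric(0)
    for (i in idx) {
      sg <- series[[i]]
      a <- sg$phase == "association"
      t <- sg$time_s[a] - assoc_start(sg)
      r <- sg$response_nm[a]
      keep <- t <= 0.9 * max(t)  # avoid plateau-dominated ill-conditioning
      dat <- data.frame(t = t[keep], r = r[keep])
      f <- tryCatch(
        suppressWarnings(
          minpack.lm::nlsLM(r ~ A * (1 - exp(-k * t)), data = dat,
                            start = list(A = max(abs(dat$r)) + 1e-9,
                                         k = 1 / stats::median(dat$t)),
                            lower = c(-Inf, 1e-8),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))),
        error = function(e) NULL)
      if (is.null(f)) next
      k_hat <- stats::coef(f)[["k"]]
      se_hat <- tryCatch(
        suppressWarnings(summary(f)$coefficients["k", "Std. Error"]),
        error = function(e) NA_real_)
      # a rate the sampling cannot resolve comes back with an enormous
      # standard error; treat it as a failed fit
      if (!is.finite(k_hat) || (is.finite(se_hat) && se_hat > 0.5 * k_hat))
        next
      est <- c(est, k_hat)
      se <- c(se, se_hat)
    }
    if (!length(est)) { dropped <- c(dropped, C); next }
    rows[[length(rows) + 1]] <-
      data.frame(conc_M = C, k_obs = mean(est), n = length(est),
                 se = sqrt(sum(se^2)) / length(se))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3)
    stop("fewer than 3 usable concentrations for the k_obs regression")
  lmfit <- stats::lm(k_obs ~ conc_M, data = tab, weights = tab$n)
  cf <- stats::coef(lmfit)
  list(k_on = unname(cf["conc_M"]), k_off = unname(cf["(Intercept)"]),
       r_squared = suppressWarnings(summary(lmfit)$r.squared),
       kobs_table = tab, dropped = dropped)
}
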