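#' Fit a 1:1 Langmuir steady-state binding isotherm
#'
#' Least-squares fit of `R_eq(C) = R_max * C / (K_D + C)` to
#' steady-state responses of a dilution series. All replicate points are
#' used unaveraged. Fits that do not converge, or whose K_D falls
#' outside `[0.01 * min(C), 100 * max(C)]` (unidentifiable, e.g. a fully
#' saturated series), are flagged unreliable.
#'
#' @param conc analyte concentrations, M (>= 4 distinct values)
#' @param response steady-state responses, nm
#' @return object of class `langmuir_fit` with elements `kd` (M),
#'   `r_max` (nm), `se` (named standard errors), `rss`, `unreliable`,
#'   `note`, `data`
#' @examples
#' C <- c(1000, 500, 250, 125, 62.5, 31.25) * 1e-6
#' fit <- fit_steady_state(C, 1.2 * C / (56e-6 + C))
#' coef(fit)
#' @export
fit_steady_state <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct concentrations")
  dat <- data.frame(conc = conc, response = response)
  r0 <- 1.05 * max(response)
  k0 <- conc[which.min(abs(response - r0 / 2))]
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ rmax * conc / (kd + conc), data = dat,
                      start = list(rmax = r0, kd = k0),
                      lower = c(1e-12, 1e-15),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, r_max = NA_real_,
                          se = c(rmax = NA_real_, kd = NA_real_),
                          rss = NA_real_, unreliable = TRUE,
                          note = "fit did not converge", data = dat,
                          fit = NULL),
                     class = "langmuir_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, kd = NA_real_))
  kd_lo <- 0.01 * min(conc[conc > 0])
  kd_hi <- 100 * max(conc)
  unrel <- cf[["kd"]] < kd_lo || cf[["kd"]] > kd_hi
  structure(list(kd = cf[["kd"]], r_max = cf[["rmax"]],
                 se = c(rmax = unname(se["rmax"]), kd = unname(se["kd"])),
                 rss = sum(stats::residuals(fit)^2),
                 unreliable = unrel,
                 note = if (unrel) "K_D outside identifiable range" else "",
                 data = dat, fit = fit),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("1:1 Langmuir steady-state fit\n")
  cat(sprintf("  K_D   = %.4g M (SE %.2g)\n", x$kd, x$se["kd"]))
  cat(sprintf("  R_max = %.4g nm (SE %.2g)\n", x$r_max, x$se["rmax"]))
  if (x$unreliable) cat("  ** flagged unreliable:", x$note, "\n")
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) {
  c(kd = object$kd, r_max = object$r_max)
}

#' @export
summary.langmuir_fit <- function(object, ...) {
  out <- data.frame(estimate = c(object$kd, object$r_max),
                    se = c(object$se["kd"], object$se["rmax"]),
                    row.names = c("K_D (M)", "R_max (nm)"))
  out
}

#' @export
predict.langmuir_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  object$r_max * conc / (object$kd + conc)
}

#' @export
residuals.langmuir_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.langmuir_fit <- function(x, ...) {
  graphics::plot(x$data$conc, x$data$response, log = "x",
                 xlab = "concentration (M)", ylab = "R_eq (nm)", ...)
  cgrid <- exp(seq(log(min(x$data$conc[x$data$conc > 0])),
                   log(max(x$data$conc)), length.out = 100))
  graphics::lines(cgrid, predict(x, cgrid))
  invisible(x)
}
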