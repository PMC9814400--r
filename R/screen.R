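#' Z-factor screening-window statistic
#'
#' `Z = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations. Values between 0.5 and 1.0 indicate an excellent
#' assay. Equal group means make the statistic undefined; `-Inf` is
#' returned with a warning.
#'
#' @param pos positive-control responses (>= 2 values)
#' @param neg negative-control responses (>= 2 values)
#' @return dimensionless Z-factor (<= 1)
#' @export
z_factor <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 values per control group")
  delta <- abs(mean(pos) - mean(neg))
  if (delta == 0) {
    warning("equal control means; Z-factor undefined")
    return(-Inf)
  }
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / delta
}

#' Call screening hits above a sigma threshold
#'
#' The hit threshold is `location + n_sigma * sigma`, where the location
#' is the median of all sample responses and sigma is their sample SD
#' (or the scaled MAD with `robust = TRUE`). Fragments above the
#' threshold are hits unless a QC flag removes them: `negative_signal`
#' (response below `-3 * sigma`), `overshoot` (response above
#' `overshoot_mult` times the positive-control mean), or any externally
#' supplied flag (e.g. `non_monotone` from [plate_responses()]).
#' A zero spread yields an empty hit set.
#'
#' @param responses named numeric vector: fragment id -> mean response, nm
#' @param n_sigma threshold multiplier (> 0)
#' @param pos_control positive-control responses (for the overshoot
#'   flag); optional
#' @param qc named character vector of external QC flags; optional
#' @param robust use median/MAD instead of median/SD
#' @param overshoot_mult overshoot multiple of the positive-control mean
#' @return object of class `screen_summary`: list with `location`,
#'   `sigma`, `threshold`, `hit_ids`, `qc_flags`, `responses`
#' @export
call_hits <- function(responses, n_sigma = 1, pos_control = NULL,
                      qc = character(0), robust = FALSE,
                      overshoot_mult = 3) {
  if (!length(responses)) stop("empty response table")
  if (n_sigma <= 0) stop("n_sigma must be > 0")
  loc <- stats::median(responses)
  sig <- if (robust) stats::mad(responses) else stats::sd(responses)
  thr <- loc + n_sigma * sig

  flags <- qc[names(qc) %in% names(responses)]
  neg_ids <- names(responses)[responses < -3 * sig]
  flags[neg_ids] <- "negative_signal"
  if (!is.null(pos_control) && length(pos_control)) {
    over <- names(responses)[responses > overshoot_mult * mean(pos_control)]
    flags[over] <- "overshoot"
  }
  hits <- if (sig == 0) character(0)
          else names(responses)[responses > thr]
  hits <- setdiff(hits, names(flags))
  structure(list(location = loc, sigma = sig, threshold = thr,
                 hit_ids = hits, qc_flags = flags,
                 responses = responses),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(paste0("Screen summary: %d fragments, threshold %.4g nm",
                     " (median %.4g + sigma %.4g)\n"),
              length(x$responses), x$threshold, x$location, x$sigma))
  cat(sprintf("  hits: %d  qc-flagged: %d\n",
              length(x$hit_ids), length(x$qc_flags)))
  if (length(x$hit_ids))
    cat("  ", paste(x$hit_ids, collapse = ", "), "\n")
  invisible(x)
}
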