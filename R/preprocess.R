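#' Align and double-reference a sensorgram
#'
#' Standard biosensor double referencing: each of the four traces is
#' first zeroed to its baseline (mean of the last `baseline_window`
#' seconds of the baseline phase), then the output is
#' `(sample - reference) - (blank - blank_reference)`. Time is re-zeroed
#' so the association phase starts at t = 0.
#'
#' @param sample sensorgram of the analyte cycle on the protein sensor
#' @param reference_sensor same cycle on the protein-free reference sensor
#' @param blank buffer-blank cycle on the protein sensor
#' @param blank_reference buffer-blank cycle on the reference sensor
#' @param baseline_window seconds of baseline used for zeroing
#' @return double-referenced `sensorgram` (attribute `referenced = TRUE`)
#' @export
align_and_double_reference <- function(sample, reference_sensor, blank,
                                       blank_reference,
                                       baseline_window = 10) {
  traces <- list(sample, reference_sensor, blank, blank_reference)
  n <- vapply(traces, nrow, integer(1))
  if (any(abs(diff(n)) > 1))
    stop("trace schedules differ by more than one sample")
  len <- min(n)
  grid <- sample$time_s[seq_len(len)]
  zeroed <- lapply(traces, function(tr) {
    r <- if (nrow(tr) == len) tr$response_nm[seq_len(len)]
         else stats::approx(tr$time_s, tr$response_nm, xout = grid,
                            rule = 2)$y
    bl <- tr$phase[seq_len(len)] == "baseline"
    t_bl <- grid[bl]
    w <- bl & grid >= max(t_bl) - baseline_window
    r - mean(r[w])
  })
  out <- sample[seq_len(len), , drop = FALSE]
  out$response_nm <- (zeroed[[1]] - zeroed[[2]]) -
                     (zeroed[[3]] - zeroed[[4]])
  out$time_s <- grid - assoc_start(out)
  attr(out, "referenced") <- TRUE
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' Steady-state response of an association phase
#'
#' `R_eq` is the mean response over the final `window` seconds of the
#' association phase. The plateau flag is true iff the magnitude of the
#' end slope (linear regression over the window) does not exceed
#' `slope_tol * max(|R_eq|, floor)` per second.
#'
#' @param sg a `sensorgram`
#' @param window averaging window, s (> 0); 10 s suits the screening
#'   schedule, 20 s the dose-response schedule
#' @param slope_tol relative slope tolerance per second
#' @param floor response floor for the slope criterion, nm
#' @return list with `r_eq` (nm), `plateau` (logical), `slope` (nm/s)
#' @export
steady_state_response <- function(sg, window = 10, slope_tol = 0.002,
                                  floor = 0.01) {
  if (window <= 0) stop("window must be > 0")
  a <- sg$phase == "association"
  t <- sg$time_s[a]; r <- sg$response_nm[a]
  if (max(t) - min(t) < window)
    stop("association phase shorter than the averaging window")
  w <- t >= max(t) - window
  r_eq <- mean(r[w])
  slope <- unname(stats::coef(stats::lm(r[w] ~ t[w]))[2])
  plateau <- abs(slope) <= slope_tol * max(abs(r_eq), floor)
  list(r_eq = r_eq, plateau = plateau, slope = slope)
}

#' Correct a plate for sensor inactivation using bracketing controls
#'
#' Positive-control cycles recorded before and after the sample block
#' define a per-sensor activity factor: the control steady-state
#' responses are normalized to the first (pre) control, and the factor is
#' interpolated linearly in cycle index between the pre and post control
#' positions. Every sample trace is divided by its cycle's factor. With
#' `mode = "n"`, traces are additionally divided by the sensor's protein
#' loading signal (attribute `loading_nm`, nm).
#'
#' @param plate a `bli_plate`
#' @param mode `"nd1"` (control correction only) or `"n"` (also
#'   normalize by the loading signal)
#' @param window steady-state window for quantifying control responses, s
#' @return the plate with corrected traces; attribute `corrected = TRUE`,
#'   and `layout$activity_factor` records the divisor used
#' @export
correct_with_controls <- function(plate, mode = c("nd1", "n"),
                                  window = 10) {
  mode <- match.arg(mode)
  lay <- plate$layout
  pos <- which(lay$role == "pos_control")
  samp <- which(lay$role == "sample")
  pre <- pos[pos < min(samp)]
  post <- pos[pos > max(samp)]
  if (!length(pre) || !length(post)) {
    warning("missing bracketing positive control; correction skipped")
    attr(plate, "corrected") <- FALSE
    return(plate)
  }
  resp <- function(i) steady_state_response(plate$traces[[i]],
                                            window = window)$r_eq
  r_pre <- mean(vapply(pre, resp, numeric(1)))
  r_post <- mean(vapply(post, resp, numeric(1)))
  c_pre <- mean(pre); c_post <- mean(post)
  # activity factor: control response interpolated in cycle index,
  # normalized to the pre-plate control
  act <- function(cycle) {
    f <- (cycle - c_pre) / (c_post - c_pre)
    (r_pre + f * (r_post - r_pre)) / r_pre
  }
  lay$activity_factor <- act(lay$cycle)
  for (i in seq_len(nrow(lay))) {
    div <- lay$activity_factor[i]
    if (mode == "n") {
      ld <- attr(plate$traces[[i]], "loading_nm")
      if (!is.null(ld)) div <- div * ld
    }
    plate$traces[[i]]$response_nm <- plate$traces[[i]]$response_nm / div
  }
  plate$layout <- lay
  attr(plate, "corrected") <- TRUE
  plate
}

#' Per-fragment steady-state responses of a screening plate
#'
#' Quantifies every cycle by its steady-state response and averages the
#' duplicate (forward/backward) measurements per fragment.
#'
#' @param plate a `bli_plate` (ideally corrected)
#' @param window steady-state window, s
#' @return list with `responses` (named vector, nm, one per fragment),
#'   `pos` / `neg` (control response vectors) and `qc` (named character
#'   vector of QC flags: `"non_monotone"` where the association phase is
#'   not monotonically accreting on average)
#' @export
plate_responses <- function(plate, window = 10) {
  lay <- plate$layout
  q <- vapply(plate$traces, function(sg)
    steady_state_response(sg, window = window)$r_eq, numeric(1))
  samp <- lay$role == "sample"
  responses <- tapply(q[samp], lay$fragment_id[samp], mean)
  responses <- stats::setNames(as.numeric(responses), names(responses))
  qc <- character(0)
  for (id in names(responses)) {
    idx <- which(samp & lay$fragment_id == id)
    mono <- vapply(idx, function(i) {
      sg <- plate$traces[[i]]
      a <- sg$phase == "association"
      stats::coef(stats::lm(sg$response_nm[a] ~ sg$time_s[a]))[2] >= 0
    }, logical(1))
    if (!all(mono)) qc[id] <- "non_monotone"
  }
  list(responses = responses,
       pos = q[lay$role == "pos_control"],
       neg = q[lay$role == "blank"],
       qc = qc)
}
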