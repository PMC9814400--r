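#' Assay schedule
#'
#' Phase durations of a BLI cycle. The screening preset is 15 s baseline,
#' 60 s association, 300 s dissociation; the dose-response preset is
#' 15 s / 120 s / 180 s.
#'
#' @param t_baseline,t_assoc,t_dissoc phase durations, s (> 0)
#' @param sampling_rate samples per second, Hz
#' @return object of class `assay_schedule`
#' @export
assay_schedule <- function(t_baseline = 15, t_assoc = 60, t_dissoc = 300,
                           sampling_rate = 5) {
  stopifnot(t_baseline > 0, t_assoc > 0, t_dissoc > 0, sampling_rate > 0)
  structure(list(t_baseline = t_baseline, t_assoc = t_assoc,
                 t_dissoc = t_dissoc, sampling_rate = sampling_rate),
            class = "assay_schedule")
}

#' @rdname assay_schedule
#' @export
schedule_screen <- function() assay_schedule(15, 60, 300)

#' @rdname assay_schedule
#' @export
schedule_dose <- function() assay_schedule(15, 120, 180)

#' Noise and artifact specification for simulated sensorgrams
#'
#' @param sigma_noise per-sample additive Gaussian noise SD, nm (>= 0)
#' @param drift_rate linear baseline drift, nm/s
#' @param unspecific_slope non-saturating linear accretion during
#'   association, nm/s per M of analyte
#' @param jump_dmso step offset (solvent mismatch) present during the
#'   association phase, nm
#' @param seed integer seed; `NA` draws from the current RNG stream
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(sigma_noise = 0, drift_rate = 0,
                       unspecific_slope = 0, jump_dmso = 0, seed = NA) {
  stopifnot(sigma_noise >= 0)
  structure(list(sigma_noise = sigma_noise, drift_rate = drift_rate,
                 unspecific_slope = unspecific_slope,
                 jump_dmso = jump_dmso, seed = seed),
            class = "noise_spec")
}

#' Simulate a single sensorgram
#'
#' Closed-form 1:1 (or 2:1, for a two-site model) binding trace with
#' baseline, association and dissociation phases plus the artifact
#' components of the noise specification. Association follows
#' `R(t) = R_eq(C) (1 - exp(-k_obs t))` per site; dissociation decays
#' exponentially from the association end value with each site's `k_off`.
#' The unspecific component accrues linearly during association and is
#' held during dissociation.
#'
#' @param model a [kinetic_model()]
#' @param conc analyte concentration, M (>= 0)
#' @param schedule an [assay_schedule()]
#' @param noise a [noise_spec()]
#' @param activity multiplicative sensor-activity factor applied to the
#'   specific signal (models protein inactivation across a plate)
#' @return a `sensorgram`: data frame with columns `time_s`,
#'   `response_nm`, `phase`, carrying the concentration and schedule as
#'   attributes
#' @export
simulate_sensorgram <- function(model, conc, schedule = schedule_screen(),
                                noise = noise_spec(), activity = 1) {
  stopifnot(inherits(model, "kinetic_model"),
            inherits(schedule, "assay_schedule"))
  if (!is.finite(conc) || conc < 0)
    stop("analyte concentration must be finite and >= 0")
  if (!is.na(noise$seed)) set.seed(noise$seed)

  dt <- 1 / schedule$sampling_rate
  t_total <- schedule$t_baseline + schedule$t_assoc + schedule$t_dissoc
  time_s <- seq(0, t_total, by = dt)
  t_a <- schedule$t_baseline
  t_d <- schedule$t_baseline + schedule$t_assoc
  phase <- ifelse(time_s < t_a, "baseline",
                  ifelse(time_s < t_d, "association", "dissociation"))

  resp <- numeric(length(time_s))
  assoc <- phase == "association"
  diss <- phase == "dissociation"
  sites <- model$sites
  if (conc > 0) {
    a <- site_assoc(sites, conc, time_s[assoc] - t_a)
    a <- matrix(a, ncol = nrow(sites))
    resp[assoc] <- rowSums(a)
    end <- site_assoc(sites, conc, schedule$t_assoc)
    d <- vapply(seq_len(nrow(sites)), function(i)
      end[i] * exp(-sites$k_off[i] * (time_s[diss] - t_d)),
      numeric(sum(diss)))
    resp[diss] <- rowSums(matrix(d, ncol = nrow(sites)))
  }
  resp <- resp * activity

  # artifact components
  resp <- resp + noise$drift_rate * time_s
  unspec <- numeric(length(time_s))
  unspec[assoc] <- noise$unspecific_slope * conc * (time_s[assoc] - t_a)
  unspec[diss] <- noise$unspecific_slope * conc * schedule$t_assoc
  resp <- resp + unspec
  resp[assoc] <- resp[assoc] + noise$jump_dmso
  if (noise$sigma_noise > 0)
    resp <- resp + stats::rnorm(length(resp), 0, noise$sigma_noise)

  sg <- data.frame(time_s = time_s, response_nm = resp, phase = phase,
                   stringsAsFactors = FALSE)
  attr(sg, "conc_M") <- conc
  attr(sg, "schedule") <- schedule
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: %d samples, C = %.4g M, phases %s\n",
              nrow(x), attr(x, "conc_M"),
              paste(unique(x$phase), collapse = "/")))
  invisible(x)
}

#' @export
plot.sensorgram <- function(x, ...) {
  graphics::plot(x$time_s, x$response_nm, type = "l",
                 xlab = "time (s)", ylab = "response (nm)", ...)
  graphics::abline(v = assoc_start(x), lty = 3)
  graphics::abline(v = dissoc_start(x), lty = 3)
  invisible(x)
}

assoc_start <- function(sg) min(sg$time_s[sg$phase == "association"])
dissoc_start <- function(sg) min(sg$time_s[sg$phase == "dissociation"])

#' Simulate a dose-response dilution series
#'
#' Two-fold (1:1) dilution ladder from `top_conc` with `n_conc` steps,
#' each measured `n_rep` times with independent noise, mirroring a
#' six-point 1000-to-31.3 uM series measured in duplicate.
#'
#' @inheritParams simulate_sensorgram
#' @param top_conc highest concentration, M (> 0)
#' @param n_conc number of concentrations (>= 2)
#' @param n_rep replicates per concentration (>= 1)
#' @return list of `sensorgram`s with `conc_M` and `replicate` attributes
#' @export
simulate_dose_series <- function(model, schedule = schedule_dose(),
                                 noise = noise_spec(), top_conc = 1e-3,
                                 n_conc = 6, n_rep = 2) {
  stopifnot(top_conc > 0, n_conc >= 2)
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (!is.na(noise$seed)) set.seed(noise$seed)
  noise$seed <- NA
  concs <- top_conc / 2^(seq_len(n_conc) - 1)
  out <- list()
  for (C in concs) for (r in seq_len(n_rep)) {
    sg <- simulate_sensorgram(model, C, schedule, noise)
    attr(sg, "replicate") <- r
    out[[length(out) + 1]] <- sg
  }
  out
}

#' Plate layout and truth specification for a simulated screen
#'
#' @param n_fragments number of library fragments on the plate
#' @param fragment_conc screening concentration, M (default 500 uM)
#' @param n_controls_pos,n_controls_neg control cycles placed before and
#'   after the sample block (each count applies to both ends)
#' @param true_binders named list: fragment id -> [kinetic_model()]
#' @param decay_half_life sensor-activity half-life across the plate, s
#'   (`Inf` = no decay)
#' @param pos_control_model kinetic model of the positive control
#' @param pos_control_conc positive-control concentration, M
#' @return object of class `plate_spec`
#' @export
plate_spec <- function(n_fragments, fragment_conc = 500e-6,
                       n_controls_pos = 2, n_controls_neg = 2,
                       true_binders = list(), decay_half_life = Inf,
                       pos_control_model = kinetic_model(5e4, 0.01, 1),
                       pos_control_conc = 500e-9) {
  stopifnot(n_fragments >= 1, fragment_conc > 0, decay_half_life > 0,
            n_controls_pos >= 1, n_controls_neg >= 0)
  ids <- sprintf("F%03d", seq_len(n_fragments))
  bad <- setdiff(names(true_binders), ids)
  if (length(bad))
    stop("true_binders not on the plate: ", paste(bad, collapse = ", "))
  structure(list(n_fragments = n_fragments, fragment_ids = ids,
                 fragment_conc = fragment_conc,
                 n_controls_pos = n_controls_pos,
                 n_controls_neg = n_controls_neg,
                 true_binders = true_binders,
                 decay_half_life = decay_half_life,
                 pos_control_model = pos_control_model,
                 pos_control_conc = pos_control_conc),
            class = "plate_spec")
}

#' Simulate a screening plate
#'
#' Every fragment is measured twice (one forward pass over the plate,
#' one backward pass); positive (ADP-like) and negative (buffer) control
#' cycles bracket the sample block. Sensor activity decays exponentially
#' with elapsed assay time: `exp(-ln2 * elapsed / decay_half_life)`
#' multiplies the specific response.
#'
#' @param spec a [plate_spec()]
#' @param schedule an [assay_schedule()]
#' @param noise a [noise_spec()]
#' @return object of class `bli_plate`: list with `traces` (list of
#'   `sensorgram`s, one per cycle) and `layout` (data frame: cycle, role,
#'   fragment_id, conc_M)
#' @export
simulate_screen_plate <- function(spec, schedule = schedule_screen(),
                                  noise = noise_spec()) {
  stopifnot(inherits(spec, "plate_spec"))
  if (spec$n_fragments < 1) stop("empty fragment list")
  if (!is.na(noise$seed)) set.seed(noise$seed)
  noise$seed <- NA

  fwd <- spec$fragment_ids
  bwd <- rev(fwd)
  roles <- c(rep("pos_control", spec$n_controls_pos),
             rep("blank", spec$n_controls_neg),
             rep("sample", length(fwd) + length(bwd)),
             rep("pos_control", spec$n_controls_pos),
             rep("blank", spec$n_controls_neg))
  frag <- c(rep(NA_character_, spec$n_controls_pos + spec$n_controls_neg),
            fwd, bwd,
            rep(NA_character_, spec$n_controls_pos + spec$n_controls_neg))
  n_cyc <- length(roles)
  cyc_dur <- schedule$t_baseline + schedule$t_assoc + schedule$t_dissoc

  inert <- kinetic_model(10, 1, 1e-12)  # no measurable specific signal
  traces <- vector("list", n_cyc)
  layout <- data.frame(cycle = seq_len(n_cyc), role = roles,
                       fragment_id = frag, conc_M = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_cyc)) {
    act <- exp(-log(2) * (i - 1) * cyc_dur / spec$decay_half_life)
    if (roles[i] == "pos_control") {
      m <- spec$pos_control_model; C <- spec$pos_control_conc
    } else if (roles[i] == "blank") {
      m <- inert; C <- 0
    } else {
      C <- spec$fragment_conc
      m <- spec$true_binders[[frag[i]]]
      if (is.null(m)) m <- inert
    }
    layout$conc_M[i] <- C
    sg <- simulate_sensorgram(m, C, schedule, noise, activity = act)
    attr(sg, "cycle") <- i
    attr(sg, "role") <- roles[i]
    attr(sg, "fragment_id") <- frag[i]
    traces[[i]] <- sg
  }
  structure(list(traces = traces, layout = layout, schedule = schedule),
            class = "bli_plate")
}

#' @export
print.bli_plate <- function(x, ...) {
  cat(sprintf("BLI plate: %d cycles (%d samples, %d controls)\n",
              nrow(x$layout), sum(x$layout$role == "sample"),
              sum(x$layout$role != "sample")))
  invisible(x)
}

#' Simulate an STD-NMR saturation build-up table
#'
#' `STD(t) = STD_max (1 - exp(-k_sat t))` evaluated on the seven-point
#' saturation-time grid 0.5, 0.75, 1.0, 1.5, 2.0, 3.0, 5.0 s (default),
#' plus Gaussian noise.
#'
#' @param std_max asymptotic STD effect, percent (>= 0)
#' @param k_sat saturation rate, s^-1 (> 0)
#' @param t_sats saturation times, s
#' @param noise_sd Gaussian noise SD, percent
#' @param seed integer seed (`NA`: current RNG stream)
#' @return data frame with columns `tsat_s`, `std_pct`
#' @export
simulate_std_buildup <- function(std_max, k_sat,
                                 t_sats = c(0.5, 0.75, 1, 1.5, 2, 3, 5),
                                 noise_sd = 0, seed = NA) {
  stopifnot(std_max >= 0, k_sat > 0)
  if (length(t_sats) == 0) stop("t_sats must be non-empty")
  if (!is.na(seed)) set.seed(seed)
  std <- std_max * (1 - exp(-k_sat * t_sats))
  if (noise_sd > 0) std <- std + stats::rnorm(length(std), 0, noise_sd)
  data.frame(tsat_s = t_sats, std_pct = std)
}

#' Simulate paired HSQC peak lists (apo and ligand-bound)
#'
#' Bound-state peaks equal the apo peaks plus the planted per-residue
#' (delta-H, delta-N) perturbations plus Gaussian noise; unperturbed
#' residues move only by noise.
#'
#' @param residues unique residue identifiers
#' @param perturbed named list: residue -> c(dH, dN) shifts in ppm
#' @param noise_sd Gaussian position noise SD, ppm (applied to both
#'   dimensions of the bound state)
#' @param seed integer seed (`NA`: current RNG stream)
#' @return list with data frames `apo` and `bound`
#'   (columns `residue`, `dH_ppm`, `dN_ppm`)
#' @export
simulate_peak_shifts <- function(residues, perturbed = list(),
                                 noise_sd = 0, seed = NA) {
  if (anyDuplicated(residues)) stop("residues must be unique")
  bad <- setdiff(names(perturbed), as.character(residues))
  if (length(bad))
    stop("perturbed residue not in residues: ", paste(bad, collapse = ", "))
  if (!is.na(seed)) set.seed(seed)
  n <- length(residues)
  apo <- data.frame(residue = residues,
                    dH_ppm = stats::runif(n, 6.5, 9.5),
                    dN_ppm = stats::runif(n, 105, 130))
  bound <- apo
  for (r in names(perturbed)) {
    i <- match(r, as.character(residues))
    bound$dH_ppm[i] <- bound$dH_ppm[i] + perturbed[[r]][1]
    bound$dN_ppm[i] <- bound$dN_ppm[i] + perturbed[[r]][2]
  }
  if (noise_sd > 0) {
    bound$dH_ppm <- bound$dH_ppm + stats::rnorm(n, 0, noise_sd)
    bound$dN_ppm <- bound$dN_ppm + stats::rnorm(n, 0, noise_sd)
  }
  list(apo = apo, bound = bound)
}

#' Simulate a solvent-probe trajectory with a planted hotspot
#'
#' Each frame places the designated probe atom (atom 1) inside the
#' spherical hotspot with probability `p_bound`, otherwise uniformly in
#' the box; all remaining probe atoms are uniform in the box.
#'
#' @param n_frames number of frames
#' @param n_probe_atoms probe atoms per frame (>= 1)
#' @param box box edge lengths, Angstrom (length 1 or 3); box spans
#'   `[0, box]` in each dimension
#' @param hotspot list with `center` (length-3, Angstrom) and `radius`
#' @param p_bound binding probability per frame, in `[0, 1]`
#' @param seed integer seed (`NA`: current RNG stream)
#' @return array of dimension `(n_probe_atoms, 3, n_frames)` with the
#'   box and hotspot as attributes
#' @export
simulate_occupancy_trajectory <- function(n_frames, n_probe_atoms = 1,
                                          box = 30,
                                          hotspot = list(center = c(15, 15, 15),
                                                         radius = 2),
                                          p_bound = 0.5, seed = NA) {
  stopifnot(n_frames >= 1, n_probe_atoms >= 1)
  if (p_bound < 0 || p_bound > 1) stop("p_bound must be in [0, 1]")
  box <- rep(box, length.out = 3)
  if (any(hotspot$center - hotspot$radius < 0) ||
      any(hotspot$center + hotspot$radius > box))
    stop("hotspot lies outside the box")
  if (!is.na(seed)) set.seed(seed)
  traj <- array(NA_real_, dim = c(n_probe_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    for (a in seq_len(n_probe_atoms)) {
      if (a == 1 && stats::runif(1) < p_bound) {
        # uniform in the hotspot sphere
        repeat {
          p <- stats::runif(3, -1, 1)
          if (sum(p^2) <= 1) break
        }
        traj[a, , f] <- hotspot$center + hotspot$radius * p
      } else {
        traj[a, , f] <- stats::runif(3, 0, box)
      }
    }
  }
  attr(traj, "box") <- box
  attr(traj, "hotspot") <- hotspot
  traj
}
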