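# Shared fixtures, all generated in code.

# reference 1:1 binder: K_D = 56 uM
ref_model <- function() kinetic_model(k_on = 1e4, k_off = 0.56, r_max = 1.2)

# dose-response schedule at reduced sampling density for fast tests
fast_dose_schedule <- function() assay_schedule(15, 120, 180, sampling_rate = 2)

clean_series <- function(model = ref_model(), noise = noise_spec(),
                         schedule = fast_dose_schedule(), top_conc = 1e-3) {
  simulate_dose_series(model, schedule, noise, top_conc = top_conc)
}

# brute-force occupancy oracle: per-frame voxel counting, no shared code
# with accumulate_grid
brute_force_grid <- function(traj, atoms, origin, dim, spacing = 1) {
  counts <- array(0, dim = dim)
  for (f in seq_len(base::dim(traj)[3])) {
    seen <- character(0)
    for (a in atoms) {
      iv <- floor((traj[a, , f] - origin) / spacing) + 1
      key <- paste(iv, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      counts[iv[1], iv[2], iv[3]] <- counts[iv[1], iv[2], iv[3]] + 1
    }
  }
  counts / base::dim(traj)[3]
}
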