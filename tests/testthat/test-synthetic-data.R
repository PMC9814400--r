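test_that("simulated sensorgrams obey the closed-form 1:1 solution", {
  m <- kinetic_model(5e3, 0.05, 1)

  # no analyte, no noise -> identically zero
  sg0 <- simulate_sensorgram(m, 0, schedule_screen(), noise_spec())
  expect_true(all(sg0$response_nm == 0))

  # Langmuir midpoint: at C = K_D the plateau is R_max / 2
  expect_equal(r_eq(m, kd(m)), 0.5)
  expect_equal(r_eq(m, 9 * kd(m)), 0.9)  # R_eq(9 K_D) = 0.9 R_max

  # closed-form spot check: k_on 5e3, k_off 0.05, C 10 uM -> k_obs 0.1;
  # response at t = 10 s into association equals R_eq (1 - e^-1)
  C <- 1e-5
  expect_equal(k_obs(m, C), 0.1)
  sg <- simulate_sensorgram(m, C, schedule_screen(), noise_spec())
  t10 <- sg$time_s == 15 + 10
  expect_equal(sg$response_nm[t10], r_eq(m, C) * (1 - exp(-1)),
               tolerance = 1e-12)

  expect_error(simulate_sensorgram(m, -1e-6), "concentration")
})

test_that("dose series forms the two-fold ladder with replicates", {
  ser <- clean_series()
  concs <- vapply(ser, function(s) attr(s, "conc_M"), numeric(1))
  expect_equal(sort(unique(concs)),
               sort(c(1000, 500, 250, 125, 62.5, 31.25) * 1e-6))
  expect_true(all(table(concs) == 2))
  expect_error(simulate_dose_series(ref_model(), n_rep = 0), "n_rep")
})

test_that("plate simulation brackets samples with controls and decays", {
  spec <- plate_spec(10, true_binders = list(F003 = ref_model()))
  pl <- simulate_screen_plate(spec, schedule_screen(),
                              noise_spec(seed = 7))
  lay <- pl$layout
  samp <- which(lay$role == "sample")
  expect_true(all(which(lay$role == "pos_control") < min(samp) |
                  which(lay$role == "pos_control") > max(samp)))
  # forward/backward: duplicate order reversed between passes
  ids <- lay$fragment_id[samp]
  expect_equal(ids[1:10], rev(ids[11:20]))

  # no decay -> bracketing control responses equal (noiseless)
  pl0 <- simulate_screen_plate(plate_spec(4), schedule_screen(),
                               noise_spec())
  q <- vapply(pl0$traces[pl0$layout$role == "pos_control"], function(s)
    steady_state_response(s)$r_eq, numeric(1))
  expect_equal(max(q) - min(q), 0, tolerance = 1e-12)

  expect_error(plate_spec(0), "n_fragments")
  expect_error(plate_spec(3, true_binders = list(F009 = ref_model())),
               "not on the plate")
})

test_that("STD build-up and peak-shift generators match their models", {
  b <- simulate_std_buildup(50, 0.8)
  expect_equal(nrow(b), 7)
  expect_equal(range(b$tsat_s), c(0.5, 5.0))
  expect_equal(b$std_pct, 50 * (1 - exp(-0.8 * b$tsat_s)))
  # asymptote
  expect_equal(simulate_std_buildup(50, 0.8, t_sats = 1e6)$std_pct, 50)
  expect_error(simulate_std_buildup(50, 0.8, t_sats = numeric(0)),
               "non-empty")

  ps <- simulate_peak_shifts(1:20, noise_sd = 0, seed = 1)
  expect_identical(ps$apo, ps$bound)
  ps2 <- simulate_peak_shifts(1:20, list(`7` = c(0.05, 0.5)), seed = 1)
  expect_equal(ps2$bound$dH_ppm[7] - ps2$apo$dH_ppm[7], 0.05)
  expect_error(simulate_peak_shifts(1:5, list(`9` = c(0.1, 0))),
               "not in residues")
})

test_that("generators are seed-deterministic", {
  n <- noise_spec(sigma_noise = 0.02, seed = 42)
  s1 <- simulate_sensorgram(ref_model(), 1e-4, schedule_screen(), n)
  s2 <- simulate_sensorgram(ref_model(), 1e-4, schedule_screen(), n)
  expect_identical(s1, s2)

  t1 <- simulate_occupancy_trajectory(50, 3, seed = 5)
  t2 <- simulate_occupancy_trajectory(50, 3, seed = 5)
  expect_identical(t1, t2)

  p1 <- simulate_screen_plate(plate_spec(5), schedule_screen(),
                              noise_spec(sigma_noise = 0.01, seed = 3))
  p2 <- simulate_screen_plate(plate_spec(5), schedule_screen(),
                              noise_spec(sigma_noise = 0.01, seed = 3))
  expect_identical(p1$traces, p2$traces)
})

test_that("occupancy trajectory respects p_bound limits", {
  hs <- list(center = c(15.5, 15.5, 15.5), radius = 0.4)
  tr1 <- simulate_occupancy_trajectory(200, 1, box = 30, hotspot = hs,
                                       p_bound = 1, seed = 2)
  g <- accumulate_grid(tr1, atoms = 1)
  expect_equal(max(g$values), 1.0)  # probe always in the hotspot voxel

  # p_bound = 0: occupancy of any voxel is ~ voxel/box volume ratio
  tr0 <- simulate_occupancy_trajectory(4000, 1, box = 20,
                                       hotspot = list(center = c(10, 10, 10),
                                                      radius = 1),
                                       p_bound = 0, seed = 2)
  g0 <- accumulate_grid(tr0, atoms = 1, origin = c(0, 0, 0),
                        dim = c(20L, 20L, 20L))
  p <- 1 / 8000  # 1 A^3 voxel in a 20 A box
  expect_lt(abs(mean(g0$values) - p), 3 * sqrt(p * (1 - p) / 4000))

  expect_error(simulate_occupancy_trajectory(
    10, 1, box = 10, hotspot = list(center = c(9, 9, 9), radius = 3)),
    "outside the box")
  expect_error(simulate_occupancy_trajectory(10, 1, p_bound = 1.2),
               "p_bound")
})
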