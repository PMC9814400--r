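make_trace <- function(model = ref_model(), conc = 1e-4,
                       noise = noise_spec(), sched = schedule_screen()) {
  simulate_sensorgram(model, conc, sched, noise)
}

test_that("double referencing removes references, blanks and drift", {
  s <- make_trace()
  # sample identical to reference, blank identical to blank reference
  out <- align_and_double_reference(s, s, s, s)
  expect_true(all(abs(out$response_nm) < 1e-12))
  expect_equal(min(out$time_s[out$phase == "association"]), 0)

  # constant baseline offset is zeroed away
  zero <- make_trace(conc = 0)
  off <- s; off$response_nm <- off$response_nm + 0.37
  out2 <- align_and_double_reference(off, zero, zero, zero)
  expect_equal(mean(out2$response_nm[out2$phase == "baseline"]), 0,
               tolerance = 1e-12)

  # drift common to sample and blank cancels
  dn <- noise_spec(drift_rate = 0.002)
  s_d <- make_trace(noise = dn)
  blank_d <- make_trace(conc = 0, noise = dn)
  out3 <- align_and_double_reference(s_d, zero, blank_d, zero)
  clean <- align_and_double_reference(s, zero, zero, zero)
  expect_equal(out3$response_nm, clean$response_nm, tolerance = 1e-10)
})

test_that("double referencing is linear in its inputs", {
  set.seed(11)
  a <- make_trace(noise = noise_spec(sigma_noise = 0.01))
  b <- make_trace(conc = 5e-4, noise = noise_spec(sigma_noise = 0.01))
  zero <- make_trace(conc = 0)
  ab <- a; ab$response_nm <- a$response_nm + b$response_nm
  lhs <- align_and_double_reference(ab, zero, zero, zero)$response_nm
  rhs <- align_and_double_reference(a, zero, zero, zero)$response_nm +
         align_and_double_reference(b, zero, zero, zero)$response_nm
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("steady-state quantification flags plateaus correctly", {
  sched <- schedule_screen()
  # constant association at 0.5 nm
  sg <- make_trace(conc = 0)
  sg$response_nm[sg$phase == "association"] <- 0.5
  ss <- steady_state_response(sg)
  expect_equal(ss$r_eq, 0.5)
  expect_true(ss$plateau)

  # pure linear ramp (unspecific accretion) never plateaus
  ramp <- make_trace(kinetic_model(10, 1e-5, 1e-9), conc = 5e-4,
                     noise = noise_spec(unspecific_slope = 2))
  expect_false(steady_state_response(ramp)$plateau)

  # noiseless 1:1 with k_obs * t_assoc >= 5 reaches R_eq within 1%
  m <- kinetic_model(1e4, 0.05, 1)   # k_obs(100 uM) = 1.05 /min... (=0.105/s)
  sg3 <- make_trace(m, conc = 1e-4)
  ss3 <- steady_state_response(sg3)
  expect_true(ss3$plateau)
  expect_equal(ss3$r_eq, r_eq(m, 1e-4), tolerance = 0.01)

  expect_error(steady_state_response(sg, window = 0), "window")
})

test_that("plateau flag is monotone in the unspecific slope", {
  slopes <- c(0, 0.05, 0.2, 1, 5)
  flags <- vapply(slopes, function(u) {
    sg <- make_trace(ref_model(), conc = 5e-4,
                     noise = noise_spec(unspecific_slope = u))
    steady_state_response(sg)$plateau
  }, logical(1))
  # TRUE may turn FALSE as the slope grows, never the reverse
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("bracketing-control correction undoes sensor decay", {
  # hand-checkable interpolation: controls 0.70 pre / 0.56 post,
  # sample midway -> divisor 0.63 / 0.70 = 0.90
  lay <- data.frame(cycle = 1:3,
                    role = c("pos_control", "sample", "pos_control"),
                    fragment_id = c(NA, "F001", NA),
                    conc_M = c(5e-7, 5e-4, 5e-7))
  mk <- function(level) {
    sg <- make_trace(conc = 0)
    sg$response_nm[sg$phase != "baseline"] <- level
    sg
  }
  pl <- structure(list(traces = list(mk(0.70), mk(1.0), mk(0.56)),
                       layout = lay), class = "bli_plate")
  cor <- correct_with_controls(pl)
  expect_equal(cor$layout$activity_factor[2], 0.90)
  a <- cor$traces[[2]]$phase == "association"
  expect_equal(unique(cor$traces[[2]]$response_nm[a]), 1 / 0.90)

  # simulator/corrector round trip: identical binders early and late on
  # a decaying plate agree after correction
  spec <- plate_spec(12, true_binders = list(F001 = ref_model(),
                                             F012 = ref_model()),
                     decay_half_life = 3e4)
  pl2 <- simulate_screen_plate(spec, schedule_screen(), noise_spec())
  cor2 <- correct_with_controls(pl2)
  r <- plate_responses(cor2)$responses
  expect_equal(unname(r["F001"]), unname(r["F012"]), tolerance = 0.02)

  # missing bracket -> warning, data untouched
  pl3 <- structure(list(traces = pl$traces[2], layout = lay[2, ]),
                   class = "bli_plate")
  expect_warning(correct_with_controls(pl3), "missing bracketing")
})

test_that("correction factors are scale-free", {
  spec <- plate_spec(6, true_binders = list(F002 = ref_model()),
                     decay_half_life = 2e4)
  pl <- simulate_screen_plate(spec, schedule_screen(), noise_spec())
  pls <- pl
  for (i in seq_along(pls$traces))
    pls$traces[[i]]$response_nm <- pls$traces[[i]]$response_nm * 3.7
  r1 <- plate_responses(correct_with_controls(pl))
  r2 <- plate_responses(correct_with_controls(pls))
  expect_equal(r2$responses / r1$responses,
               rep(3.7, length(r1$responses)), ignore_attr = TRUE)
})
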