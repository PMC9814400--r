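test_that("grid accumulation matches definitions and the brute-force oracle", {
  # one static atom -> single voxel at occupancy 1
  traj <- array(rep(c(0.2, 0.2, 0.2), 5), dim = c(1, 3, 5))
  g <- accumulate_grid(traj, origin = c(0, 0, 0), dim = c(3L, 3L, 3L))
  expect_equal(g$values[1, 1, 1], 1)
  expect_equal(sum(g$values), 1)

  # two atoms in the same voxel in one frame count once
  traj2 <- array(c(0.1, 0.5, 0.5, 0.9, 0.5, 0.5), dim = c(2, 3, 1))
  g2 <- accumulate_grid(traj2, origin = c(0, 0, 0), dim = c(2L, 2L, 2L))
  expect_equal(max(g2$values), 1)
  expect_equal(sum(g2$values), 1)
  # ... unless atom-count densities are requested
  g2d <- accumulate_grid(traj2, origin = c(0, 0, 0), dim = c(2L, 2L, 2L),
                         count_atoms = TRUE)
  expect_equal(sum(g2d$values), 2)

  # oracle equivalence on random frames
  set.seed(17)
  traj3 <- simulate_occupancy_trajectory(50, 4, box = 12,
                                         hotspot = list(center = c(6, 6, 6),
                                                        radius = 2),
                                         p_bound = 0.5, seed = 17)
  g3 <- accumulate_grid(traj3, origin = c(0, 0, 0),
                        dim = c(12L, 12L, 12L))
  oracle <- brute_force_grid(traj3, 1:4, c(0, 0, 0), c(12, 12, 12))
  expect_identical(g3$values, oracle)
  expect_true(all(g3$values >= 0 & g3$values <= 1))
})

test_that("replica grids sum voxel-wise", {
  trs <- lapply(1:4, function(s)
    simulate_occupancy_trajectory(300, 1, box = 12,
                                  hotspot = list(center = c(6, 6, 6),
                                                 radius = 1.5),
                                  p_bound = 0.6, seed = s))
  grids <- lapply(trs, accumulate_grid, atoms = 1, origin = c(0, 0, 0),
                  dim = c(12L, 12L, 12L))
  gsum <- sum_grids(grids)
  expect_equal(gsum$values, Reduce(`+`, lapply(grids, `[[`, "values")))
  expect_equal(gsum$n_replicas, 4L)
  # identity and linearity
  zero <- grids[[1]]; zero$values[] <- 0
  expect_equal(sum_grids(list(grids[[1]], zero))$values, grids[[1]]$values)
  expect_equal(sum_grids(list(grids[[1]], grids[[1]]))$values,
               2 * grids[[1]]$values)
  bad <- grids[[1]]; bad$origin <- bad$origin + 1
  expect_error(sum_grids(list(grids[[1]], bad)), "geometries")
})

test_that("top sites find the planted hotspot with deterministic ties", {
  tr <- simulate_occupancy_trajectory(2000, 3, box = 24,
                                      hotspot = list(center = c(8, 12, 16),
                                                     radius = 1.5),
                                      p_bound = 0.9, seed = 23)
  g <- accumulate_grid(tr)
  sites <- top_sites(g, k = 2, min_separation = 6)
  expect_equal(nrow(sites), 2)
  d1 <- sqrt(sum((unlist(sites[1, c("x", "y", "z")]) -
                  c(8, 12, 16))^2))
  expect_lt(d1, 2.5)                      # top-1 is the planted site
  expect_gt(sites$occupancy[1], 5 * sites$occupancy[2])

  # uniform grid: ties resolved by lexicographic voxel index
  gu <- g; gu$values[] <- 0.5
  s1 <- top_sites(gu, k = 3, min_separation = 2)
  s2 <- top_sites(gu, k = 3, min_separation = 2)
  expect_identical(s1, s2)
  expect_equal(s1$x[1], g$origin[1] + 0.5)

  # k = 1 with two distant equal peaks returns exactly one site
  gg <- g; gg$values[] <- 0
  gg$values[2, 2, 2] <- 1; gg$values[20, 20, 20] <- 1
  expect_equal(nrow(top_sites(gg, k = 1)), 1)
})

test_that("site residues use a strict distance cutoff", {
  structure <- data.frame(
    x = c(5.9, 6.0, 2, 0), y = 0, z = 0,
    resno = c(10, 11, 12, 12),
    resid = c("ARG", "HIS", "GLU", "GLU"))
  res <- site_residues(c(0, 0, 0), structure, cutoff = 6)
  expect_true(10 %in% res$resno)       # 5.9 A: inside
  expect_false(11 %in% res$resno)      # exactly 6.0 A: excluded
  expect_true(12 %in% res$resno)
  expect_equal(res$min_dist[res$resno == 12], 0)

  # brute-force distance oracle on a synthetic 100-residue structure
  set.seed(29)
  big <- data.frame(x = runif(500, -20, 20), y = runif(500, -20, 20),
                    z = runif(500, -20, 20),
                    resno = rep(1:100, each = 5))
  ctr <- c(1, -2, 3)
  got <- site_residues(ctr, big)$resno
  d <- sqrt((big$x - ctr[1])^2 + (big$y - ctr[2])^2 + (big$z - ctr[3])^2)
  want <- sort(unique(big$resno[d < 6]))
  expect_equal(got, want)
})

test_that("binding-event detection is monotone in the run length", {
  hs <- list(center = c(10, 10, 10), radius = 2)
  tr <- simulate_occupancy_trajectory(400, 1, box = 20, hotspot = hs,
                                      p_bound = 0.85, seed = 37)
  starts <- sapply(c(3, 10, 25, 60), function(nc) {
    ev <- detect_binding_event(tr, hs$center, cutoff = 6, n_consec = nc)
    if (is.null(ev)) Inf else ev$start
  })
  expect_true(all(diff(starts) >= 0))
})

test_that("representative pose lands in the hotspot and breaks ties low", {
  hs <- list(center = c(10, 10, 10), radius = 2)
  reps <- lapply(1:3, function(s)
    simulate_occupancy_trajectory(500, 1, box = 20, hotspot = hs,
                                  p_bound = 0.9, seed = 40 + s))
  grids <- lapply(reps, accumulate_grid, origin = c(0, 0, 0),
                  dim = c(20L, 20L, 20L))
  gsum <- sum_grids(grids)
  ivs <- lapply(reps, detect_binding_event, center = hs$center)
  pose <- representative_pose(reps, ivs, gsum)
  expect_false(is.null(pose))
  expect_lt(sqrt(sum((pose$pose - hs$center)^2)), hs$radius + 1e-9)

  # degenerate interval of identical frames: zero RMSD, first frame
  still <- array(rep(c(5, 5, 5), 20), dim = c(1, 3, 20))
  p2 <- representative_pose(list(still), list(list(start = 1, end = 20)),
                            gsum)
  expect_equal(p2$rmsd, 0)
  expect_equal(p2$frame, 1)
})
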