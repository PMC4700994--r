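test_that("drift-only update follows (D/kBT) F dt exactly", {
  cfg <- sim_config(noise_enabled = FALSE, timestep = 0.01)
  p0 <- data.frame(x = 0, y = 0, z = 0)
  expect_equal(step_overdamped(p0, cfg, matrix(0, 1, 3)),
               as_position_matrix(p0))
  p1 <- step_overdamped(p0, cfg, matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.numeric(p1[1, 1]), 0.2 / kbt300 * 0.01,
               tolerance = 1e-12)
  expect_equal(as.numeric(p1[1, 1]), 0.003355, tolerance = 1e-3)
  expect_error(step_overdamped(p0, cfg, matrix(c(NaN, 0, 0), 1, 3)),
               "non-finite force")
})

test_that("a harmonic trap reaches the Ornstein-Uhlenbeck stationary variance", {
  cfg <- sim_config(seed = 11, timestep = 0.01, recording_interval = 0.01)
  r <- ionpmf:::run_brownian(flat_landscape(), cfg, cbind(0, 0, 0), "ion",
                             n_steps = 1e6, seed = 42,
                             bias_k = matrix(c(0, 0, 1), 1, 3),
                             bias_center = matrix(0, 1, 3))
  expect_equal(var(r$frames$z), kbt300, tolerance = 0.05)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  cfg <- sim_config(seed = 3, timestep = 0.01, recording_interval = 0.05)
  ls <- single_well()
  run <- function(seed) ionpmf:::run_brownian(ls, cfg, cbind(0, 0, 0.5), "ion",
                                              n_steps = 2000, seed = seed)
  expect_identical(run(7)$frames, run(7)$frames)
  expect_false(identical(run(7)$frames$z, run(8)$frames$z))
})

test_that("equilibrium sampling recovers Boltzmann statistics", {
  # single well: -kBT log(histogram) reproduces the potential within 0.1
  sw <- single_well(center = 0, depth = -2, width = 1.5)
  cfg <- sim_config(seed = 7, timestep = 0.01, recording_interval = 0.25,
                    z_bounds = c(-8, 8))
  h <- sample_equilibrium(sw, cfg, n_frames = 4e5, bin_width = 0.5)
  truth <- axial_potential(sw, h$z)$energy
  ok <- !is.na(h$f_est) & h$count > 1000
  dev <- h$f_est[ok] - (truth[ok] - min(truth))
  expect_lt(max(abs(dev - mean(dev))), 0.25)

  # flat potential on a bounded interval: uniform occupancy
  # thinned to ~one box-relaxation time per frame so counts are ~independent
  cfgf <- sim_config(seed = 5, timestep = 0.01, recording_interval = 5,
                     z_bounds = c(-4, 4))
  hf <- sample_equilibrium(flat_landscape(lateral_k = 0.5), cfgf,
                           n_frames = 2e4, bin_width = 1)
  expect_gt(chisq.test(hf$count)$p.value, 0.01)
  expect_error(sample_equilibrium(sw, cfg, n_frames = 100), "1e3")
})

test_that("two wells are occupied in the Boltzmann ratio", {
  dw <- landscape_spec("asym",
    axial_features = data.frame(center = c(-2, 2), depth = c(-2, -1),
                                width = c(0.8, 0.8)))
  cfg <- sim_config(seed = 19, timestep = 0.01, recording_interval = 0.1,
                    z_bounds = c(-5, 5))
  h <- sample_equilibrium(dw, cfg, n_frames = 4e5, bin_width = 0.5)
  n_deep <- sum(h$count[h$z > -3.5 & h$z < -0.5])
  n_shallow <- sum(h$count[h$z > 0.5 & h$z < 3.5])
  ratio <- n_shallow / n_deep
  # wells differ by 1 kcal/mol -> ratio exp(-1/kBT) = 0.187; allow generous CI
  expect_equal(ratio, exp(-1 / kbt300), tolerance = 0.25)
})

test_that("solvent point sets are uniform, Poisson-distributed and seeded", {
  expect_equal(nrow(generate_solvent_points(5, c(0, 30), 0, seed = 1)), 0)
  pts <- generate_solvent_points(5, c(-10, 20), 0.02, seed = 4)
  expect_true(all(pts$x^2 + pts$y^2 <= 25))
  expect_true(all(pts$z >= -10 & pts$z <= 20))
  expect_identical(pts, generate_solvent_points(5, c(-10, 20), 0.02, seed = 4))
  counts <- vapply(1:200, function(s)
    nrow(generate_solvent_points(5, c(0, 30), 0.033, seed = s)), numeric(1))
  mu <- 0.033 * pi * 25 * 30
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 200))
  expect_error(generate_solvent_points(-1, c(0, 1), 1), "radius")
})

test_that("the stability bound refuses an unstable timestep", {
  cfg <- sim_config(timestep = 0.5, recording_interval = 1)
  expect_error(
    ionpmf:::run_brownian(preset_landscape("K-like"), cfg,
                          cbind(0, 0, -12), "K-like", n_steps = 10, seed = 1),
    "stability")
})
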