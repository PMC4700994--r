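test_that("the Jarzynski estimator matches hand-computed values", {
  expect_equal(estimate_delta_F(rep(1.7, 5), 300)$dF, 1.7)
  # three-sample log-mean-exp, computed by hand
  expect_equal(estimate_delta_F(c(0, 0, 1.192), 300)$dF, 0.2027,
               tolerance = 1e-3)
  # huge work values must not underflow thanks to log-sum-exp
  expect_true(is.finite(estimate_delta_F(c(5000, 5002), 300)$dF))
  expect_equal(estimate_delta_F(c(5000, 5000), 300)$dF, 5000)
  expect_error(estimate_delta_F(numeric(0)), "empty")
})

test_that("Gaussian work distributions give dF = mu - sigma^2/(2 kBT)", {
  set.seed(1)
  W <- rnorm(1e5, mean = 2, sd = 0.5)
  est <- estimate_delta_F(W, 300)
  expect_equal(est$dF, 2 - 0.25 / (2 * kbt300), tolerance = 0.02)
  expect_equal(2 - 0.25 / (2 * kbt300), 1.790, tolerance = 1e-3)
})

test_that("the estimate respects Jensen's bound and sample permutation", {
  set.seed(42)
  for (i in 1:50) {
    W <- rnorm(sample(2:50, 1), mean = runif(1, -2, 4), sd = runif(1, 0, 3))
    est <- estimate_delta_F(W, 300)$dF
    expect_lte(est, mean(W) + 1e-12)
    expect_equal(est, estimate_delta_F(sample(W), 300)$dF, tolerance = 1e-12)
  }
})

test_that("the variance formula evaluates exactly", {
  expect_equal(variance_of_estimate(0, 10), 0)
  expect_equal(variance_of_estimate(0.596, 100, 300), 0.073, tolerance = 1e-2)
  expect_equal(variance_of_estimate(1.192, 2, 300), 1.885, tolerance = 1e-3)
  expect_error(variance_of_estimate(1, 1), "Q")
})

test_that("profiles accumulate per-step estimates from a zero anchor", {
  sched <- c(-20, -19, -18, -17)
  p <- profile_from_steps(c(1, -1, 0), sched)
  expect_equal(p$dF, c(0, 1, 0, 0))
  expect_equal(p$lambda, sched)
  flat <- profile_from_steps(rep(0, 3), sched)
  expect_equal(flat$dF, rep(0, 4))
  expect_error(profile_from_steps(c(1, 2), sched), "length mismatch")
  # concatenation: profile of a long schedule equals stitched sub-profiles
  steps <- c(0.5, -0.2, 0.9, 0.1, -0.3)
  full <- profile_from_steps(steps, 0:5)
  front <- profile_from_steps(steps[1:2], 0:2)
  back <- profile_from_steps(steps[3:5], 2:5)
  expect_equal(full$dF, c(front$dF, back$dF[-1] + front$dF[3]))
})

test_that("per-ion components sum to the total and collapse for one ion", {
  cfg <- sim_config(timestep = 0.01, recording_interval = 5)
  sp <- pull_spec(k_axial = 0.6, lambda_start = 0, lambda_increment = 0.5,
                  n_steps = 6, tau = 10, n_replicas = 8,
                  initial_placement = data.frame(x = 0, y = 0, z = c(0, -2)),
                  seed = 5)
  run <- run_pulling(flat_landscape(lateral_k = 0.5), sp, cfg,
                     keep_frames = FALSE)
  prof <- jarzynski_profile(run)
  expect_equal(prof$dF_ion1 + prof$dF_ion2, prof$dF, tolerance = 1e-8)
  sp1 <- pull_spec(k_axial = 0.6, lambda_start = 0, lambda_increment = 0.5,
                   n_steps = 6, tau = 10, n_replicas = 8,
                   initial_placement = data.frame(x = 0, y = 0, z = 0),
                   seed = 5)
  run1 <- run_pulling(flat_landscape(lateral_k = 0.5), sp1, cfg,
                      keep_frames = FALSE)
  prof1 <- jarzynski_profile(run1)
  expect_equal(prof1$dF_ion1, prof1$dF, tolerance = 1e-10)
  # independent per-ion estimates exist but need not sum to the total
  indep <- per_ion_profiles(run, method = "independent")
  expect_true(all(is.finite(indep$dF_ion1)))
})

test_that("two symmetric ions receive equal components within uncertainty", {
  cfg <- sim_config(timestep = 0.01, recording_interval = 5)
  sp <- pull_spec(k_axial = 0.6, lambda_start = 0, lambda_increment = 0.5,
                  n_steps = 8, tau = 20, n_replicas = 20,
                  xy_center = c(0, 0),
                  initial_placement = data.frame(x = c(0, 0), y = c(1, -1),
                                                 z = c(0, 0)),
                  seed = 9)
  run <- run_pulling(flat_landscape(lateral_k = 0.5), sp, cfg,
                     keep_frames = FALSE)
  prof <- jarzynski_profile(run)
  n <- nrow(prof)
  expect_lt(abs(prof$dF_ion1[n] - prof$dF_ion2[n]),
            2 * prof$dF_se[n] + 0.2)
})
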