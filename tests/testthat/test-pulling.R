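test_that("schedules reproduce the canonical inward and outward protocols", {
  inward <- build_schedule(pull_spec(lambda_start = -20, lambda_increment = 1,
                                     n_steps = 19))
  expect_length(inward, 19)
  expect_equal(inward[1], -20)
  expect_equal(inward[19], -2)
  expect_equal(diff(inward), rep(1, 18))
  outward <- build_schedule(pull_spec(lambda_start = 4.5,
                                      lambda_increment = -1, n_steps = 23))
  expect_equal(outward[23], -17.5)
  expect_equal(build_schedule(pull_spec(lambda_start = 3, n_steps = 1)), 3)
  expect_error(pull_spec(lambda_increment = 0, n_steps = 5), "zero")
})

test_that("restraint energy is the documented harmonic form", {
  sp <- pull_spec(k_axial = 0.6)
  expect_equal(restraint_energy(c(0, 0, -15), -15, sp), 0)
  # 2 A lateral deviation at k = 0.6 is the ~2 kBT lateral bias
  expect_equal(restraint_energy(c(2, 0, -15), -15, sp), 1.2)
  sp1 <- pull_spec(k_axial = 1)
  expect_equal(restraint_energy(c(0, 0, -14), -15, sp1), 0.5)
  expect_gt(restraint_energy(c(0.1, -0.2, -14.7), -15, sp), 0)
})

test_that("switch work is the frozen-coordinate energy difference", {
  sp <- pull_spec(k_axial = 0.6)
  w <- switch_work(-15, -15, -14, sp)
  expect_equal(w$dW, 0.3)
  expect_equal(switch_work(c(-12, -13), -13, -13, sp)$dW, 0)
  w3 <- switch_work(c(-15, -15, -15), -15, -14, sp)
  expect_equal(w3$dW, 0.9)
  expect_equal(w3$per_ion, rep(0.3, 3))
})

test_that("pulling runs are reproducible and satisfy the work bookkeeping", {
  cfg <- sim_config(timestep = 0.01, recording_interval = 2)
  sp <- pull_spec(k_axial = 0.6, lambda_start = 0, lambda_increment = 1,
                  n_steps = 6, tau = 10, n_replicas = 3,
                  initial_placement = data.frame(x = 0, y = 0, z = c(0, -3)),
                  seed = 21)
  ls <- flat_landscape(lateral_k = 0.5)
  r1 <- run_pulling(ls, sp, cfg)
  r2 <- run_pulling(ls, sp, cfg)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$trajectory, r2$trajectory)
  for (rep in unique(r1$ledger$replica)) {
    d <- r1$ledger[r1$ledger$replica == rep, ]
    expect_equal(d$W_cum, cumsum(d$dW), tolerance = 1e-10)
    expect_equal(d$dW, d$dW_ion1 + d$dW_ion2, tolerance = 1e-10)
  }
  expect_identical(r1$direction, "inward")
  expect_true(all(diff(r1$trajectory$time[r1$trajectory$replica == 1 &
                                            r1$trajectory$ion == 1]) > 0))
})

test_that("with noise off an ion tracking lambda pays 0.5 k dlambda^2 per step", {
  cfg <- sim_config(timestep = 0.01, noise_enabled = FALSE,
                    recording_interval = 5)
  sp <- pull_spec(k_axial = 1, k_lateral = 0.5, lambda_start = 0,
                  lambda_increment = 1, n_steps = 5, tau = 40, n_replicas = 1,
                  initial_placement = data.frame(x = 0, y = 0, z = 0),
                  seed = 1)
  r <- run_pulling(flat_landscape(), sp, cfg)
  expect_equal(r$ledger$dW, rep(0.5, 4), tolerance = 1e-3)
  expect_equal(max(r$ledger$W_cum), 2, tolerance = 5e-3)
})

test_that("replica seed streams are order-independent", {
  expect_identical(seed_stream(42L, 3), seed_stream(42L, 3))
  expect_false(seed_stream(42L, 3) == seed_stream(42L, 4))
  expect_false(seed_stream(42L, 3) == seed_stream(43L, 3))
  expect_true(seed_stream(2147483646, 1e6) < 2^31)
})
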