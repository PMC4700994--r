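test_that("axial histograms conserve counts and locate constructed peaks", {
  tr <- make_traj(z1 = rep(-12, 50), z2 = rep(-9, 50))
  h <- axial_histograms(tr, bin_width = 0.5)
  expect_equal(sum(h$count[h$ion == 1]), 50)
  expect_equal(sum(h$count[h$ion == 2]), 50)
  expect_equal(sum(h$count[h$ion == 1] > 0), 1)
  set.seed(3)
  mix <- make_traj(z1 = rnorm(4000, -13, 0.5), z2 = rnorm(4000, -5, 0.5))
  hm <- axial_histograms(mix, bin_width = 0.5)
  peak1 <- hm$z[hm$ion == 1][which.max(hm$count[hm$ion == 1])]
  peak2 <- hm$z[hm$ion == 2][which.max(hm$count[hm$ion == 2])]
  expect_lt(abs(peak1 + 13), 0.5 + 1e-9)
  expect_lt(abs(peak2 + 5), 0.5 + 1e-9)
  expect_error(axial_histograms(mix[0, ]), "empty")
})

test_that("pair density bins frames over (z1, z2)", {
  tr <- make_traj(z1 = -12, z2 = -9, time = 1)
  m <- pair_density(tr, z_range = c(-16, -4))
  expect_equal(sum(m$counts), 1)
  expect_equal(m$counts[which(m$axes[[1]]$mids == -11.75),
                        which(m$axes[[2]]$mids == -8.75)], 1)
  set.seed(8)
  tr2 <- make_traj(z1 = rnorm(2000, -12, 0.7), z2 = rnorm(2000, -9, 0.7))
  m2 <- pair_density(tr2, z_range = c(-17.5, -4))
  expect_equal(sum(m2$counts), m2$total_frames)
  sym <- pair_density(tr2, z_range = c(-17.5, -4), symmetrize = TRUE)
  expect_equal(sym$counts, t(sym$counts))
  expect_error(pair_density(tr2[tr2$ion == 1, ]), "2 ions")
})

test_that("block detection fires on a diagonal blob and only there", {
  set.seed(21)
  n_blob <- 1200; n_bg <- 800
  # 60% of mass in a 3.5 A stretch of the diagonal band around z = -12
  z <- runif(n_blob, -13.7, -10.3)
  dz <- runif(n_blob, -0.45, 0.45)
  blob <- make_traj(z1 = z + dz / 2, z2 = z - dz / 2, time = 1:n_blob)
  bg <- make_traj(z1 = runif(n_bg, -16, -12), z2 = runif(n_bg, -8, -4.5),
                  time = n_blob + 1:n_bg)
  m <- pair_density(dplyr::bind_rows(blob, bg), z_range = c(-17.5, -4))
  rep <- detect_block(m, delta_diag = 1, theta_occ = 0.2)
  expect_true(rep$detected)
  expect_equal(rep$extent, 3.5, tolerance = 0.5 / 3.5)
  expect_gt(rep$occupancy, 0.5)
  # the same blob moved off the diagonal is not a block
  off <- make_traj(z1 = z + 2, z2 = z - 2, time = 1:n_blob)
  m_off <- pair_density(dplyr::bind_rows(off, bg), z_range = c(-17.5, -4))
  expect_false(detect_block(m_off, 1, 0.2)$detected)
  # uniform occupancy never concentrates 20% in the band
  unif <- make_traj(z1 = runif(6000, -16, -4.5), z2 = runif(6000, -16, -4.5),
                    time = 1:6000)
  expect_false(detect_block(pair_density(unif, z_range = c(-17.5, -4)),
                            1, 0.2)$detected)
})

test_that("block detection is invariant to ion relabelling after symmetrization", {
  set.seed(12)
  z <- runif(900, -13, -11); dz <- runif(900, -0.4, 0.4)
  tr <- make_traj(z1 = z + dz, z2 = z - dz, time = 1:900)
  swapped <- tr
  swapped$ion <- 3L - swapped$ion
  a <- detect_block(pair_density(tr, symmetrize = TRUE))
  b <- detect_block(pair_density(swapped, symmetrize = TRUE))
  expect_equal(a$z_lo, b$z_lo)
  expect_equal(a$occupancy, b$occupancy)
})

test_that("shared-solvent counts use the two-sphere overlap, per frame", {
  tr <- make_traj(z1 = -10, z2 = -6, time = 1)   # ions 4 A apart
  mid <- tibble::tibble(time = 1, x = 0, y = 0, z = -8)
  s <- separation_and_solvent(tr, mid)
  expect_equal(s$mean_r12, 4)
  expect_equal(s$mean_shared, 1)   # midpoint is 2 A from each ion
  far <- tibble::tibble(time = 1, x = 0, y = 0, z = -20)
  expect_equal(separation_and_solvent(tr, far)$mean_shared, 0)
  # brute-force oracle on random points
  set.seed(33)
  pts <- tibble::tibble(time = 1, x = runif(1000, -6, 6),
                        y = runif(1000, -6, 6), z = runif(1000, -14, -2))
  got <- separation_and_solvent(tr, pts)$mean_shared
  d1 <- sqrt(pts$x^2 + pts$y^2 + (pts$z + 10)^2)
  d2 <- sqrt(pts$x^2 + pts$y^2 + (pts$z + 6)^2)
  expect_equal(got, sum(d1 <= 4 & d2 <= 4))
  # misaligned solvent times are an error
  late <- tibble::tibble(time = 2, x = 0, y = 0, z = -8)
  expect_error(separation_and_solvent(tr, late), "aligned")
})

test_that("asymmetry summaries reduce to arithmetic on simple profiles", {
  lam <- seq(-20, -2)
  mk_prof <- function(dF) ionpmf:::new_free_energy_profile(
    tibble::tibble(lambda = lam, dF = dF, dF_se = 0.1))
  flat <- mk_prof(rep(0, length(lam)))
  a0 <- asymmetry_summary(flat, flat)
  expect_equal(a0$difference, 0)
  expect_equal(a0$escape_difference, 0)
  rise <- mk_prof(pmin(8, pmax(0, lam + 14)))       # climbs to 8 inside filter
  low <- mk_prof(pmin(3, pmax(0, (lam + 14) / 2)))  # climbs to 3
  a <- asymmetry_summary(rise, low)
  expect_equal(a$max_work_inward, 8)
  expect_equal(a$max_work_outward, 3)
  expect_equal(a$difference, 5)
  disjoint <- mk_prof(rep(0, length(lam)))
  disjoint$lambda <- lam + 100
  expect_error(asymmetry_summary(rise, disjoint), "non-overlapping")
})
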