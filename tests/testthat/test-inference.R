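test_that("kinetic arithmetic helpers reproduce the worked numbers", {
  expect_equal(memory_distance_kb(700, 66), 770)
  expect_equal(traversal_time_min(517, 71), 7.28, tolerance = 0.001)
  expect_equal(round(traversal_time_min(517, 71) + 5), 12)
  expect_equal(0.2 * 49, 9.8) # chasing speed from the arc ratio
})

test_that("pre-existing fraction is exact on the analytic profile", {
  g <- test_genome()
  for (f in c(0, 0.18, 0.5)) {
    prof <- analytic_t0_profile(f, g)
    expect_equal(estimate_pre_existing_fraction(prof), f, tolerance = 1e-10)
  }
  flat <- profile1d(rep(1, smcollide:::n_bins(g, 1e4)), g, 1e4, kind = "MFA")
  expect_equal(estimate_pre_existing_fraction(flat), 0)
  bad <- profile1d(rep(0, smcollide:::n_bins(g, 1e4)), g, 1e4, kind = "MFA")
  expect_error(estimate_pre_existing_fraction(bad), "not positive")
})

test_that("pre-existing fraction is recovered from a simulated population", {
  g <- test_genome()
  cells <- init_population(replisome_params(f_pre = 0.18), g, 5000, seed = 21)
  f <- estimate_pre_existing_fraction(compute_mfa(cells, g))
  expect_lt(abs(f - 0.18), 0.02)
})

test_that("initiation fraction handles the degenerate limits exactly", {
  g <- test_genome()
  nb <- smcollide:::n_bins(g, 1e4)
  t0 <- profile1d(rep(1, nb), g, 1e4, kind = "MFA",
                  normalization = "copy_number")
  ctr <- abs(smcollide:::bin_centers_signed(g, 1e4))
  # all cells initiated, none pre-existing, boundary at 1 Mb
  mid <- profile1d(1 + (ctr <= 1e6), g, 1e4, kind = "MFA",
                   normalization = "copy_number")
  expect_equal(estimate_initiation_fraction(mid, t0), 1)
  expect_equal(estimate_initiation_fraction(t0, t0), 0) # none initiated
  expect_error(estimate_initiation_fraction(
    mid, profile1d(rep(1, 10), genome_spec(length = 1e5), 1e4, kind = "MFA")),
    "same genome")
})

test_that("motor speed estimation is a per-arm least-squares slope", {
  df <- data.frame(time = c(10, 15), extent = c(715, 1072))
  expect_equal(as.numeric(estimate_motor_speed(df)), 71.4)
  flat <- data.frame(time = c(10, 15, 20), extent = c(400, 400, 400))
  expect_equal(as.numeric(estimate_motor_speed(flat)), 0)
  expect_error(estimate_motor_speed(df[1, ]), "2 time points")
})

test_that("fork speed estimation needs a detectable moving boundary", {
  g <- test_genome()
  nb <- smcollide:::n_bins(g, 1e4)
  flat <- profile1d(rep(1, nb), g, 1e4, kind = "MFA")
  tc <- list(`10` = flat, `20` = flat)
  expect_error(estimate_fork_speed(tc), "boundary")
  expect_error(estimate_fork_speed(list(`10` = flat)), "2 time points")
})

test_that("bypass delays follow the deficit arithmetic", {
  d1 <- estimate_bypass_delay(1000, 871, 71) # one-sided: ~129 kb deficit
  expect_equal(d1$minutes, 129 / 71, tolerance = 1e-9)
  expect_equal(d1$rounded, 2)
  d2 <- estimate_bypass_delay(1000, 817, 71) # two-sided: ~183 kb deficit
  expect_equal(d2$rounded, 3)
  expect_equal(estimate_bypass_delay(500, 500, 71)$minutes, 0)
  expect_error(estimate_bypass_delay(500, 600, 71), "exceeds")
  expect_error(estimate_bypass_delay(500, 400, 0), "positive")
})

test_that("goodness of fit is scale-free, masked and positive definite", {
  g <- test_genome()
  nb <- smcollide:::n_bins(g, 1e4)
  set.seed(31)
  v <- runif(nb, 10, 100)
  a <- profile1d(v, g, 1e4, kind = "OCCUPANCY")
  b <- profile1d(sample(v), g, 1e4, kind = "OCCUPANCY")
  expect_equal(gof_score(a, a), 0)
  expect_gt(gof_score(b, a), 0)
  # invariant to common rescaling
  a10 <- profile1d(10 * v, g, 1e4, kind = "OCCUPANCY")
  expect_equal(gof_score(a10, a), 0)
  expect_equal(gof_score(b, a10), gof_score(b, a))
  expect_error(gof_score(a, a, mask = rep(TRUE, nb)), "masked")
  # parS-proximal bins are masked by default
  v2 <- v
  pb <- smcollide:::bin_of(g$parS_bp, g, 1e4)
  v2[pb] <- v[pb] * 50
  expect_equal(gof_score(profile1d(v2, g, 1e4, kind = "OCCUPANCY"), a), 0)
})

test_that("a degenerate collision sweep returns its only cell", {
  scn <- scenario("FIG5B")
  g <- scn$genome
  ts <- scn$sample_times[1]
  sim <- simulate_joint(scn$protocol, scn$rep_params, scn$smc_params, g, 15,
                        seed = 41, sample_times = ts)
  ref <- compute_occupancy(sim$snapshots[[1]]$smcs, g, bin_size = 1e4)
  sw <- sweep_collision_params(scn, 30, 120, ref, n_cells = 15, seed = 42,
                               sample_time = ts)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$best$tau_unload, 30)
  expect_true(sw$best$in_ratio_region)
})
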