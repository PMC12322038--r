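test_that("init_population honours the pre-existing fraction limits", {
  g <- test_genome()
  p0 <- init_population(replisome_params(f_pre = 0), g, 200, seed = 1)
  expect_true(all(!p0$initiated))
  expect_true(all(p0$left_pos == 0 & p0$right_pos == 0))
  p1 <- init_population(replisome_params(f_pre = 1), g, 200, seed = 1)
  expect_true(all(p1$initiated))
  expect_true(all(p1$left_pos < 0 & p1$right_pos > 0))
  expect_equal(-p1$left_pos, p1$right_pos) # equal progress on both arms
  # reproducible for a given seed
  expect_identical(init_population(replisome_params(), g, 50, seed = 7),
                   init_population(replisome_params(), g, 50, seed = 7))
})

test_that("fully pre-existing population matches the closed-form MFA decay", {
  # uniform fork progress: expected copy number 1 + (1 - x/(L/2))
  g <- test_genome()
  cells <- init_population(replisome_params(f_pre = 1), g, 20000, seed = 2)
  mfa <- compute_mfa(cells, g)
  ctr <- abs(smcollide:::bin_centers_signed(g, 10000))
  expected <- 1 + (1 - ctr / (g$length / 2))
  expect_lt(max(abs(mfa$values - expected)), 0.02)
})

test_that("step_forks moves, stalls and freezes forks as the protocol dictates", {
  g <- test_genome()
  rp <- replisome_params(p_stall = 0)
  env42 <- list(temperature = 42, initiation_allowed = FALSE,
                forks_stalled = FALSE, smc_loading_active = FALSE)
  cells <- data.frame(cell = 1, initiated = TRUE, left_pos = -100000,
                      right_pos = 100000, left_stalled = FALSE,
                      right_stalled = FALSE, completed = FALSE)
  out <- step_forks(cells, env42, rp, g, dt = 10)
  expect_equal(out$left_pos, -100000 - 66 * 1000 * 10) # linear motion at v42
  # a spontaneously stalled fork does not move
  cells$left_stalled <- TRUE
  out <- step_forks(cells, env42, rp, g, dt = 10)
  expect_equal(out$left_pos, -100000)
  expect_equal(out$right_pos, 100000 + 660000)
  # HPUra freezes everything in place
  envH <- env42; envH$forks_stalled <- TRUE
  out <- step_forks(cells, envH, rp, g, dt = 10)
  expect_equal(out$right_pos, 100000)
  expect_error(step_forks(cells, env42, rp, g, dt = 0), "dt")
})

test_that("without stalling all initiated cells complete and MFA flattens at 2", {
  g <- test_genome()
  rp <- replisome_params(f_pre = 0, t_init_mean = 0.01, p_stall = 0)
  pr <- protocol_events(perm_start = 0, perm_dur = 15, samples = c(50))
  snaps <- simulate_replication(pr, rp, g, n_cells = 100, seed = 3)
  final <- snaps[["50"]]
  expect_true(all(final$completed))
  mfa <- compute_mfa(final, g)
  expect_equal(unname(mfa$values), rep(2, length(mfa$values)))
})

test_that("population MFA stays in [1,2] and is monotone from ori to ter", {
  g <- test_genome()
  pr <- protocol_events(perm_start = 0, perm_dur = 15, samples = c(0, 10, 25))
  snaps <- simulate_replication(pr, replisome_params(p_stall = 0), g,
                                n_cells = 1500, seed = 4)
  for (s in snaps) {
    mfa <- compute_mfa(s, g)
    expect_true(all(mfa$values >= 1 & mfa$values <= 2))
    for (a in smcollide:::arm_views(mfa)) {
      # non-increasing with ori distance, up to Monte-Carlo noise
      expect_true(all(diff(a$v) <= 0.03))
    }
  }
})

test_that("HPUra-frozen time courses keep the MFA unchanged", {
  g <- test_genome()
  pr <- protocol_events(perm_start = 0, perm_dur = 15, hpura = 15,
                        samples = c(20, 30, 45))
  snaps <- simulate_replication(pr, replisome_params(), g, n_cells = 400,
                                seed = 5)
  m20 <- compute_mfa(snaps[["20"]], g)$values
  m45 <- compute_mfa(snaps[["45"]], g)$values
  expect_equal(m20, m45)
  # and the boundary regression across frozen samples reports zero speed
  profs <- lapply(snaps, compute_mfa, genome = g)
  expect_equal(as.numeric(estimate_fork_speed(profs)), 0, tolerance = 1e-8)
})

test_that("single-cell boundary advances at the configured speed", {
  g <- test_genome()
  rp <- replisome_params(f_pre = 0, t_init_mean = 1e-6, v30 = 40, p_stall = 0)
  pr <- protocol_events(perm_start = 0, perm_dur = 15, samples = c(5, 10))
  snaps <- simulate_replication(pr, rp, g, n_cells = 1, seed = 6)
  # initiation lands within the first step; the subsequent motion is exact
  expect_lt(abs(snaps[["5"]]$right_pos - 40 * 1000 * 5), 40 * 1000 * 0.25)
  expect_equal(snaps[["10"]]$right_pos - snaps[["5"]]$right_pos, 40 * 1000 * 5)
})
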