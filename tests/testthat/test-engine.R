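test_that("no loading means no bound complexes; loading fills the pool", {
  g <- test_genome()
  prm <- smc_params(n_smc = 10)
  st <- smc_ensemble_init(5, prm)
  b <- no_barriers(5, g)
  out <- step_smcs(st, b, b, params = prm, genome = g, t_s = 0, dt = 1,
                   loading_active = FALSE)
  expect_equal(sum(out$state$bound), 0)
  set.seed(1)
  st2 <- st
  for (s in 1:600) # 10 min at full loading
    st2 <- step_smcs(st2, b, b, params = prm, genome = g, t_s = s - 1,
                     dt = 1, loading_active = TRUE)$state
  expect_gt(sum(st2$bound), 0)
  # per-cell bound count never exceeds the pool size
  expect_true(all(table(st2$cell[st2$bound]) <= prm$n_smc))
})

test_that("a blocked motor is carried with the fork and released on completion", {
  g <- test_genome()
  prm <- smc_params(engagement_model = "block_only", t_memory = 0,
                    tau_dissoc = 1e9)
  st <- smc_ensemble_init(1, prm)
  # one bound complex straddling the path of the left fork
  st$bound[1] <- TRUE
  st$load_pos[1] <- -5e5; st$pos1[1] <- -994500; st$pos2[1] <- -1e5
  st$load_time[1] <- 0; st$dissoc_time[1] <- Inf
  fork_at <- function(pos) fork_barriers(
    data.frame(cell = 1, initiated = TRUE, left_pos = pos, right_pos = 1e5,
               left_stalled = FALSE, right_stalled = FALSE,
               completed = FALSE), g)
  # head-to-tail: motor 1 (ter-ward, ~1192 bp/s) catches the slower left fork
  set.seed(2)
  out <- step_smcs(st, fork_at(-994600), fork_at(-994700), params = prm,
                   genome = g, t_s = 0, dt = 1)
  st <- out$state
  expect_true(st$blk1[1])
  expect_equal(st$pos1[1], -994700)
  # carried with the moving fork
  st <- step_smcs(st, fork_at(-994700), fork_at(-994800), params = prm,
                  genome = g, t_s = 1, dt = 1)$state
  expect_true(st$blk1[1])
  expect_equal(st$pos1[1], -994800)
  # fork reaches the terminus: category change releases the motor unblocked
  done <- fork_barriers(data.frame(cell = 1, initiated = TRUE,
                                   left_pos = -g$length / 2,
                                   right_pos = 1e5, left_stalled = FALSE,
                                   right_stalled = FALSE, completed = FALSE), g)
  st <- step_smcs(st, done, done, params = prm, genome = g, t_s = 2,
                  dt = 1)$state
  expect_false(st$blk1[1])
  expect_true(is.infinite(st$ev_t1[1]))
})

test_that("head-on pushback moves the blocked motor backward at fork speed", {
  g <- test_genome()
  prm <- smc_params(engagement_model = "block_only", tau_dissoc = 1e9)
  st <- smc_ensemble_init(1, prm)
  # ori-ward motor on the left arm meets the left fork coming at it
  st$bound[1] <- TRUE
  st$load_pos[1] <- -1.5e6; st$pos1[1] <- -1.6e6; st$pos2[1] <- -1.001e6
  st$load_time[1] <- 0; st$dissoc_time[1] <- Inf
  fork_at <- function(pos) fork_barriers(
    data.frame(cell = 1, initiated = TRUE, left_pos = pos, right_pos = 1e5,
               left_stalled = FALSE, right_stalled = FALSE,
               completed = FALSE), g)
  set.seed(3)
  st <- step_smcs(st, fork_at(-1.0005e6), fork_at(-1.0015e6), params = prm,
                  genome = g, t_s = 0, dt = 1)$state
  expect_true(st$blk2[1])
  expect_equal(st$pos2[1], -1.0015e6)
  # fork keeps moving ter-ward: motor 2 pushed backward with it
  st <- step_smcs(st, fork_at(-1.0015e6), fork_at(-1.0026e6), params = prm,
                  genome = g, t_s = 1, dt = 1)$state
  expect_equal(st$pos2[1], -1.0026e6)
})

test_that("spontaneous residence times are exponential with the configured mean", {
  g <- test_genome()
  prm <- smc_params(tau_dissoc = 180)
  scnp <- protocol_events(perm_start = NULL, samples = 21)
  rp <- replisome_params(f_pre = 0) # no forks: no collision losses
  sim <- simulate_joint(scnp, rp, prm, g, n_cells = 250, seed = 8,
                        sample_times = 21, constitutive_loading = TRUE)
  ev <- sim$unbound
  expect_true(all(ev$reason == "dissoc"))
  # complexes loaded early enough that censoring at the horizon is negligible
  early <- ev$time - ev$lifetime <= 180
  expect_gt(sum(early), 5000)
  expect_equal(mean(ev$lifetime[early]), 180, tolerance = 0.03)
})

test_that("control zipping with an ori-proximal site reaches the expected extent", {
  # loading possible from IPTG, 5-min lag; sampled 15 min after IPTG:
  # ~10 min of symmetric extrusion at 71.5 kb/min ~ 715 kb per arm,
  # compared against the measured ~730 kb within 10%
  g <- genome_spec(parS_deg = -1)
  prm <- smc_params(v_to_ori = 71.5)
  pr <- protocol_events(perm_start = NULL, iptg = 0, samples = 15)
  sim <- simulate_joint(pr, replisome_params(f_pre = 0), prm, g,
                        n_cells = 100, seed = 9, sample_times = 15)
  cm <- compute_contact_map(sim$snapshots[[1]]$smcs, g)
  ze <- zipping_extent(cm, g$parS_bp)
  expect_true(ze$detected)
  expect_lt(abs(ze$ccw - 730000) / 730000, 0.10)
  expect_lt(abs(ze$cw - 730000) / 730000, 0.10)
})

test_that("motors never sit beyond a live fork without a logged bypass", {
  scn <- scenario("FIG5B")
  g <- scn$genome
  ts <- scn$sample_times[1]
  sim <- simulate_joint(scn$protocol, scn$rep_params, scn$smc_params, g,
                        n_cells = 60, seed = 10, sample_times = ts)
  sn <- sim$snapshots[[1]]
  live <- sn$forks$initiated & !sn$forks$completed
  s <- sn$smcs[live[sn$smcs$cell], ]
  fl <- sn$forks$left_pos[s$cell]
  fr <- sn$forks$right_pos[s$cell]
  half <- g$length / 2
  eps <- scn$smc_params$bypass_offset + 1
  # loaded on the replicated (origin) side, now beyond the live fork
  beyond1 <- s$pos1 < fl - eps & fl > -half & s$load_pos >= fl
  beyond2 <- s$pos2 > fr + eps & fr < half & s$load_pos <= fr
  expect_true(all(s$n_byp1[beyond1] >= 1))
  expect_true(all(s$n_byp2[beyond2] >= 1))
  # and some bypasses genuinely happened in this collision scenario
  expect_gt(sum(s$n_byp1), 0)
})

test_that("joint simulation is reproducible for a fixed seed", {
  scn <- scenario("FIG1C")
  a <- simulate_joint(scn$protocol, scn$rep_params, scn$smc_params,
                      scn$genome, n_cells = 20, seed = 11, sample_times = 10)
  b <- simulate_joint(scn$protocol, scn$rep_params, scn$smc_params,
                      scn$genome, n_cells = 20, seed = 11, sample_times = 10)
  expect_identical(a$snapshots[[1]]$smcs, b$snapshots[[1]]$smcs)
  expect_identical(a$snapshots[[1]]$forks, b$snapshots[[1]]$forks)
})
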