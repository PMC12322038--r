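test_that("with memory off the chasing motor reaches and tracks the fork", {
  scn <- scenario("FIG7B")
  pts <- simulate_arc2(scn$smc_params, fork_speed = 66, t_memory = 0,
                       scn$protocol, scn$genome, n_pairs = 1500, seed = 5,
                       sample_time = 25, constitutive_loading = TRUE)
  fork <- attr(pts, "fork_pos")
  # the motor outruns the fork by only ~5.5 kb/min, so it has caught up
  # once its initial gap (66 kb/min x time since parS passage at loading)
  # is smaller than 5.5 kb/min x its age, with margin
  gap0 <- 66 * (pts$load_time - pts$parS_passage_time)
  age <- 25 - pts$load_time
  sel <- pts$bound & pts$loaded_after_fork & fork > -scn$genome$length / 2 &
    age > gap0 / (71.5 - 66) + 1
  expect_gt(sum(sel), 10)
  expect_lt(max(abs(pts$pos1[sel] - fork[sel])), 2000)
})

test_that("memory slows the chase: trailing arc lags far behind the fork", {
  scn <- scenario("FIG7B")
  g <- scn$genome
  parS <- g$parS_bp[1]
  pts <- simulate_arc2(scn$smc_params, 66, 700, scn$protocol, g,
                       n_pairs = 1500, seed = 5, sample_time = 18,
                       constitutive_loading = TRUE)
  sel <- pts$bound & pts$loaded_after_fork & (18 - pts$load_time) > 2
  p <- pts[sel, ]
  fork <- attr(pts, "fork_pos")[sel]
  # chasing motors sit well behind the fork (no tracking)
  expect_gt(mean(abs(p$pos1 - fork)), 100000)
  # motors loaded close behind the fork crawl at ~10 kb/min, far below
  # both the fork speed and the unhindered motor speed
  gap0 <- 66 * (p$load_time - p$parS_passage_time)
  young <- (18 - p$load_time) <= 5 & gap0 <= 66
  spd <- abs(p$pos1[young] - parS) / 1000 / (18 - p$load_time[young])
  expect_gt(sum(young), 15)
  expect_lt(mean(spd), 18)
  expect_gt(mean(spd), 3)
  # arm-speed ratio far below 1 in the young-arc regime (upward tilt)
  expect_lt(arc_speed_ratio(p[young, ], parS), 0.4)
})

test_that("a long-stalled fork imposes no slowdown (memory resolved)", {
  # all ages behind a fork stalled longer than t_memory exceed t_memory
  scn <- scenario("FIG5B") # HPUra stalls forks, SMC loads afterwards
  g <- scn$genome
  sim <- simulate_joint(scn$protocol, scn$rep_params, scn$smc_params, g,
                        n_cells = 40, seed = 12,
                        sample_times = scn$sample_times[2])
  sn <- sim$snapshots[[1]]
  # SMCs that loaded at parS more than t_memory after the stall moved at
  # full speed until reaching the fork: displacement/time = v_to_ter for
  # unblocked, not-yet-collided chasing motors
  s <- sn$smcs[sn$smcs$load_pos == g$parS_bp & !sn$smcs$blocked1 &
                 sn$smcs$n_byp1 == 0, ]
  live <- sn$forks$initiated[s$cell] & !sn$forks$completed[s$cell]
  ahead <- s$pos1 > sn$forks$left_pos[s$cell] # not yet at the fork
  s <- s[live & ahead, ]
  age <- sn$time - s$load_time
  s <- s[age > 0.5, ]; age <- age[age > 0.5]
  expect_gt(nrow(s), 10)
  spd <- abs(s$pos1 - g$parS_bp) / 1000 / age
  expect_equal(median(spd), scn$smc_params$v_to_ter, tolerance = 0.02)
})

test_that("the memory sweep recovers the generating duration", {
  scn <- scenario("FIG7B")
  g <- scn$genome
  ref <- simulate_arc2(scn$smc_params, 66, 700, scn$protocol, g, 600,
                       seed = 99, sample_time = 25,
                       constitutive_loading = TRUE)
  sw <- sweep_fork_memory(seq(400, 1000, 100), c(23, 25, 27), ref,
                          g$parS_bp[1], scn$smc_params, 66, scn$protocol, g,
                          n_pairs = 800, seed = 7,
                          constitutive_loading = TRUE)
  expect_lte(abs(sw$best_t_memory - 700), 100)
  expect_true(is.finite(sw$band) && sw$band > 0)
  # a memory-free reference pushes the fit to the grid minimum
  ref0 <- simulate_arc2(scn$smc_params, 66, 0, scn$protocol, g, 600,
                        seed = 99, sample_time = 25,
                        constitutive_loading = TRUE)
  sw0 <- sweep_fork_memory(c(100, 400, 700, 1000), 25, ref0, g$parS_bp[1],
                           scn$smc_params, 66, scn$protocol, g,
                           n_pairs = 600, seed = 7,
                           constitutive_loading = TRUE)
  expect_equal(sw0$best_t_memory, 100)
})
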