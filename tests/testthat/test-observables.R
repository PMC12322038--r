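test_that("MFA handles degenerate populations exactly", {
  g <- test_genome()
  unrep <- data.frame(cell = 1:5, initiated = FALSE, left_pos = 0,
                      right_pos = 0, left_stalled = FALSE,
                      right_stalled = FALSE, completed = FALSE)
  expect_true(all(compute_mfa(unrep, g)$values == 1))
  expect_error(compute_mfa(unrep[0, ], g), "empty")
  # all forks exactly at +/- x: step profile
  x <- 8e5
  pop <- data.frame(cell = 1:10, initiated = TRUE, left_pos = -x,
                    right_pos = x, left_stalled = FALSE,
                    right_stalled = FALSE, completed = FALSE)
  mfa <- compute_mfa(pop, g)
  ctr <- smcollide:::bin_centers_signed(g, mfa$bin_size)
  expect_true(all(mfa$values[abs(ctr) <= x - 1e4] == 2))
  expect_true(all(mfa$values[abs(ctr) >= x + 1e4] == 1))
})

test_that("MFA commutes with ensemble concatenation", {
  g <- test_genome()
  a <- init_population(replisome_params(f_pre = 0.5), g, 150, seed = 1)
  b <- init_population(replisome_params(f_pre = 0.1), g, 50, seed = 2)
  b$cell <- b$cell + 150
  both <- compute_mfa(rbind(a, b), g)$values
  mixed <- (150 * compute_mfa(a, g)$values + 50 * compute_mfa(b, g)$values) / 200
  expect_equal(both, mixed)
})

test_that("occupancy places smoothed peaks at motor positions", {
  g <- test_genome()
  s <- data.frame(pos1 = -8e5, pos2 = 4e5, load_pos = -661000)
  occ <- compute_occupancy(s, g, include_load_sites = FALSE)
  ctr <- smcollide:::bin_centers_signed(g, occ$bin_size)
  top <- order(occ$values, decreasing = TRUE)[1:12]
  expect_true(any(abs(ctr[top] + 8e5) < 2000))
  expect_true(any(abs(ctr[top] - 4e5) < 2000))
  expect_equal(sum(occ$values), 1e6) # reads-per-million normalization
  none <- compute_occupancy(s[0, ], g)
  expect_true(all(none$values == 0))
})

test_that("profile ratios behave like log2 of scaled tracks", {
  g <- test_genome()
  v <- runif(smcollide:::n_bins(g, 1000), 50, 100)
  a <- profile1d(v, g, 1000, kind = "OCCUPANCY")
  b <- profile1d(2 * v, g, 1000, kind = "OCCUPANCY")
  expect_true(all(abs(profile_ratio(a, a, pseudocount = 0)$values) < 1e-12))
  r <- profile_ratio(b, a, pseudocount = 0)
  expect_equal(r$values, rep(1, length(r$values)))
  expect_equal(r$bin_size, 5000)
  expect_error(profile_ratio(a, profile1d(v[1:100], genome_spec(length = 1e5),
                                          1000, kind = "OCCUPANCY")),
               "share genome")
})

test_that("contact maps are symmetric mixtures with a monotone background", {
  g <- test_genome()
  empty <- compute_contact_map(data.frame(pos1 = numeric(),
                                          pos2 = numeric()), g)
  m <- empty$matrix
  expect_equal(m, t(m))
  # background decays monotonically with circular distance along a row
  nb <- nrow(m)
  row1 <- m[1, ]
  d <- pmin(abs(seq_len(nb) - 1), nb - abs(seq_len(nb) - 1))
  expect_true(all(diff(row1[order(d)]) <= 1e-12))
  # a single anchor pair adds a symmetric off-diagonal peak
  one <- compute_contact_map(data.frame(pos1 = -5e5, pos2 = 5e5), g)
  i <- smcollide:::bin_of(-5e5, g, 1e4); j <- smcollide:::bin_of(5e5, g, 1e4)
  expect_equal(one$matrix[i, j], one$matrix[j, i])
  expect_gt(one$matrix[i, j], max(empty$matrix))
})

test_that("balancing equalizes row sums and preserves symmetry and mass", {
  g <- test_genome()
  set.seed(4)
  pts <- data.frame(pos1 = runif(200, -2e6, 0), pos2 = runif(200, 0, 2e6))
  cm <- compute_contact_map(pts, g)
  bal <- balance_contact_map(cm)
  rs <- rowSums(bal$matrix)
  expect_lt((max(rs) - min(rs)) / mean(rs), 0.01)
  expect_equal(bal$matrix, t(bal$matrix))
  expect_equal(sum(bal$matrix), sum(cm$matrix), tolerance = 1e-3)
})

test_that("zipping extent recovers a synthetic perpendicular diagonal", {
  g <- test_genome()
  p <- g$parS_bp
  w <- 5e5
  arc <- data.frame(pos1 = p - seq(1e4, w, by = 1e4),
                    pos2 = p + seq(1e4, w, by = 1e4))
  arc$load_pos <- p
  cm <- compute_contact_map(arc, g, kernel_sd = 10000)
  ze <- zipping_extent(cm, p)
  expect_true(ze$detected)
  expect_lt(abs(ze$ccw - w), 4e4)
  expect_lt(abs(ze$cw - w), 4e4)
  # empty map: flagged null result
  ze0 <- zipping_extent(compute_contact_map(arc[0, ], g), p)
  expect_false(ze0$detected)
  expect_true(is.na(ze0$ccw))
})

test_that("noiseless control extents grow linearly at the motor speed", {
  g <- test_genome()
  p <- g$parS_bp
  v <- 71.5
  mk <- function(tmin) {
    k <- seq(0.5, tmin, by = 0.5)
    data.frame(pos1 = p - v * 1000 * k, pos2 = p + v * 1000 * k)
  }
  ext <- vapply(c(10, 14, 18), function(tmin) {
    ze <- zipping_extent(compute_contact_map(mk(tmin), g, kernel_sd = 1e4), p)
    c(ze$ccw, ze$cw) / 1000
  }, numeric(2))
  df <- data.frame(time = c(10, 14, 18), ccw = ext[1, ], cw = ext[2, ])
  est <- estimate_motor_speed(df)
  expect_equal(as.numeric(est), v, tolerance = 0.02)
})

test_that("arc speed ratio reads the tilt of anchor displacements", {
  p <- -661000
  k <- seq(1e4, 5e5, by = 1e4)
  expect_equal(arc_speed_ratio(data.frame(pos1 = p - k, pos2 = p + k), p), 1)
  expect_equal(arc_speed_ratio(data.frame(pos1 = p - 0.2 * k, pos2 = p + k), p),
               0.2)
  expect_equal(arc_speed_ratio(data.frame(pos1 = rep(p, 20),
                                          pos2 = p + k[1:20]), p), 0)
  expect_error(arc_speed_ratio(data.frame(pos1 = p, pos2 = p), p), "3 arc")
  expect_error(arc_speed_ratio(data.frame(pos1 = rep(p, 5),
                                          pos2 = rep(p, 5)), p), "degenerate")
})
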