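#' Kinetic arithmetic helpers
#'
#' Closed-form quantities used throughout the collision analysis: the
#' physical extent of the fork-memory zone behind a fork moving at constant
#' speed, and simple traversal times.
#'
#' @param t_memory_s Memory duration in seconds.
#' @param fork_speed Fork speed in kb/min.
#' @return Memory distance in kb.
#' @export
memory_distance_kb <- function(t_memory_s, fork_speed) {
  t_memory_s / 60 * fork_speed
}

#' @rdname memory_distance_kb
#' @param distance_kb Distance in kb.
#' @param speed Translocation speed in kb/min.
#' @return Traversal time in minutes.
#' @export
traversal_time_min <- function(distance_kb, speed) {
  distance_kb / speed
}

# per-arm views of a profile: distance from ori (bp) and values, sorted
arm_views <- function(p) {
  ctr <- bin_centers_signed(p$genome, p$bin_size)
  lapply(list(left = ctr < 0, right = ctr >= 0), function(sel) {
    d <- abs(ctr[sel]); o <- order(d)
    list(d = d[o], v = p$values[sel][o])
  })
}

#' Estimate fork speed from an MFA time course
#'
#' Per arm and time point, the replicated/unreplicated boundary is the
#' position where the MFA profile crosses the midpoint between the
#' replicated (origin-proximal) and unreplicated (terminus-proximal)
#' plateaus; the speed is the least-squares slope of boundary position on
#' time, averaged over arms.
#'
#' In populations with pre-existing forks the distal (unreplicated-zone)
#' baseline rises as those forks advance, dragging the midpoint crossing
#' and biasing the slope low. Because pre-existing coverage is saturated at
#' `1 + f_pre` everywhere behind its own front -- which moves with the
#' initiated-fork front -- supplying the T = 0 profile pins the
#' unreplicated plateau at the time-invariant `1 + f_pre` (copy-number
#' scale) and removes that bias.
#'
#' @param timecourse Named list of `profile1d` MFA profiles; names are
#'   sample times in minutes.
#' @param rep_window,unrep_window Plateau windows as fractions of the arm
#'   length (distance from ori).
#' @param mfa_T0 Optional T = 0 `profile1d` (copy-number scale): fixes the
#'   unreplicated plateau at `1 + f_pre` instead of the per-time distal
#'   window mean.
#' @return Speed in kb/min (attribute `per_arm` has the two arm slopes).
#' @export
estimate_fork_speed <- function(timecourse, rep_window = c(0, 0.2),
                                unrep_window = c(0.7, 0.95),
                                mfa_T0 = NULL) {
  if (length(timecourse) < 2) stop("need at least 2 time points")
  times <- as.numeric(names(timecourse))
  if (any(is.na(times))) stop("timecourse must be named by sample time")
  L2 <- timecourse[[1]]$genome$length / 2
  base_lev <- if (is.null(mfa_T0)) NULL else
    1 + max(estimate_pre_existing_fraction(mfa_T0), 0)
  bounds <- sapply(timecourse, function(p) {
    vapply(arm_views(p), function(a) {
      rel <- a$d / L2
      rep_lev <- mean(a$v[rel >= rep_window[1] & rel <= rep_window[2]])
      unrep_lev <- if (is.null(base_lev))
        mean(a$v[rel >= unrep_window[1] & rel <= unrep_window[2]]) else
        base_lev
      if (!is.finite(rep_lev) || !is.finite(unrep_lev) ||
          rep_lev - unrep_lev < 0.02 * unrep_lev)
        return(NA_real_)
      mid <- (rep_lev + unrep_lev) / 2
      below <- which(a$v < mid)
      below <- below[below > 1]
      if (!length(below)) return(NA_real_)
      i <- below[1]
      # linear interpolation between the bracketing bins
      d0 <- a$d[i - 1]; d1 <- a$d[i]
      v0 <- a$v[i - 1]; v1 <- a$v[i]
      if (v0 == v1) d0 else d0 + (v0 - mid) / (v0 - v1) * (d1 - d0)
    }, numeric(1))
  })
  per_arm <- apply(bounds, 1, function(b) {
    ok <- is.finite(b)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(b[ok] / 1000 ~ times[ok]))[2])
  })
  if (all(is.na(per_arm))) stop("no detectable replication boundary")
  out <- mean(per_arm, na.rm = TRUE)
  attr(out, "per_arm") <- per_arm
  out
}

#' Estimate the pre-existing-fork fraction from a T = 0 MFA profile
#'
#' Under uniform pre-existing fork positions the T = 0 profile is
#' `s * (1 + f * (1 - x/(L/2)))`; the origin/terminus window ratio is
#' inverted exactly for the finite window geometry:
#' `f = (r - 1) / ((1 - chi_o) - r (1 - chi_t))` with `chi` the mean
#' relative origin distance of each window.
#'
#' @param mfa_T0 A `profile1d` from a G1-arrest (T = 0) sample.
#' @param window_frac Window half-extent as a fraction of genome length
#'   around ori and ter (default 0.05).
#' @return Estimated fraction (can exceed \[0,1\] on pathological input;
#'   not clamped).
#' @export
estimate_pre_existing_fraction <- function(mfa_T0, window_frac = 0.05) {
  L <- mfa_T0$genome$length
  L2 <- L / 2
  ctr <- bin_centers_signed(mfa_T0$genome, mfa_T0$bin_size)
  d <- abs(ctr)
  ori_w <- d <= window_frac * L
  ter_w <- d >= L2 - window_frac * L
  v_o <- mean(mfa_T0$values[ori_w])
  v_t <- mean(mfa_T0$values[ter_w])
  if (!is.finite(v_t) || v_t <= 0) stop("terminus window mean not positive")
  chi_o <- mean(d[ori_w]) / L2
  chi_t <- mean(d[ter_w]) / L2
  r <- v_o / v_t
  (r - 1) / ((1 - chi_o) - r * (1 - chi_t))
}

#' Estimate the initiation fraction from a mid-replication MFA profile
#'
#' Model: at a mid-replication time where every initiated cell has
#' replicated the origin window but no initiated fork has reached the fit
#' window, the profile is `y(x) = s (1 + F(x))` with
#' `F(x) = f_pre (1 - (x - delta)/(L/2))` in the zone only pre-existing
#' forks (advanced by `delta`) have reached, and
#' `y_ori = s (1 + f_pre + (1 - f_pre) p)` at the origin. The scale `s`
#' is recovered from the linear fit `y = A - B x` over the fit window
#' (`s = B (L/2) / f_pre`, falling back to the window mean when
#' `f_pre ~ 0`), and the initiation fraction among initially unreplicated
#' cells is `p = (y_ori/s - 1 - f_pre) / (1 - f_pre)`, clamped to \[0, 1\].
#' This reduces to the plain origin/terminus ratio correction when
#' pre-existing forks have not advanced (`delta = 0`).
#'
#' When the mid profile is on the absolute copy-number scale (an MFA track
#' as produced by [compute_mfa()], `normalization = "copy_number"`), the
#' scale is `s = 1` exactly and the slope fit is skipped; slope-based scale
#' recovery is only needed for read-sampled (relative) tracks and is
#' considerably noisier.
#'
#' @param mfa_mid Mid-replication `profile1d` (ori replicated in initiated
#'   cells; fit window still untouched by initiated forks).
#' @param mfa_T0 T = 0 `profile1d` (for the pre-existing fraction).
#' @param ori_frac Origin window as a fraction of the arm length
#'   (default 0.03, i.e. about 60 kb on each arm).
#' @param fit_window Unreplicated-zone fit window as fractions of the arm
#'   length (default c(0.55, 0.90)).
#' @param window_frac Passed to [estimate_pre_existing_fraction()].
#' @return Estimated initiation fraction in \[0, 1\].
#' @export
estimate_initiation_fraction <- function(mfa_mid, mfa_T0, ori_frac = 0.03,
                                         fit_window = c(0.55, 0.90),
                                         window_frac = 0.05) {
  if (mfa_mid$genome$length != mfa_T0$genome$length)
    stop("profiles are not on the same genome")
  f_pre <- max(estimate_pre_existing_fraction(mfa_T0, window_frac), 0)
  L2 <- mfa_mid$genome$length / 2
  ctr <- bin_centers_signed(mfa_mid$genome, mfa_mid$bin_size)
  d <- abs(ctr)
  U <- d / L2 >= fit_window[1] & d / L2 <= fit_window[2]
  if (!any(U)) stop("empty fit window")
  s <- NA_real_
  if (identical(mfa_mid$normalization, "copy_number")) {
    s <- 1
  } else if (f_pre > 0.02) {
    fit <- stats::lm(mfa_mid$values[U] ~ d[U])
    B <- -unname(stats::coef(fit)[2])
    if (is.finite(B) && B > 0) s <- B * L2 / f_pre
  }
  if (!is.finite(s)) # flat baseline: scale is the window mean
    s <- mean(mfa_mid$values[U]) / (1 + f_pre * (1 - mean(d[U]) / L2))
  y_ori <- mean(mfa_mid$values[d / L2 <= ori_frac])
  if (!is.finite(y_ori)) stop("empty origin window")
  min(max((y_ori / s - 1 - f_pre) / (1 - f_pre), 0), 1)
}

#' Estimate per-motor SMC speed from zipping-extent growth
#'
#' Least-squares slope of zipping extent on time, per arm, averaged.
#'
#' @param extent_timecourse Data.frame with a `time` column (minutes) and
#'   one column per arm of zipping extents in kb.
#' @return Speed in kb/min (attribute `per_arm`).
#' @export
estimate_motor_speed <- function(extent_timecourse) {
  stopifnot(is.data.frame(extent_timecourse), "time" %in% names(extent_timecourse))
  if (nrow(extent_timecourse) < 2) stop("need at least 2 time points")
  arms <- setdiff(names(extent_timecourse), "time")
  per_arm <- vapply(arms, function(a) {
    unname(stats::coef(stats::lm(extent_timecourse[[a]] ~
                                   extent_timecourse$time))[2])
  }, numeric(1))
  out <- mean(per_arm)
  attr(out, "per_arm") <- per_arm
  out
}

#' Infer the pre-bypass pause from a zipping-extent deficit
#'
#' The distance by which zipping in a collision experiment lags the
#' matched no-collision control, divided by the motor speed, is the mean
#' delay experienced before bypassing the replisome.
#'
#' @param extent_control,extent_collision Extents in kb (control >=
#'   collision).
#' @param motor_speed Motor speed in kb/min.
#' @return List with `minutes` (raw) and `rounded` (nearest whole minute,
#'   mirroring how such delays are usually reported).
#' @export
estimate_bypass_delay <- function(extent_control, extent_collision,
                                  motor_speed) {
  if (motor_speed <= 0) stop("motor speed must be positive")
  deficit <- extent_control - extent_collision
  if (deficit < 0) stop("collision extent exceeds control extent")
  m <- deficit / motor_speed
  list(minutes = m, rounded = round(m))
}

#' Goodness-of-fit score between two profiles
#'
#' Sum of squared residuals of the unit-sum-normalized profiles over
#' unmasked bins; scale-free (invariant to common rescaling) and
#' deterministic. Lower is better.
#'
#' @param sim,ref `profile1d` objects on the same binning.
#' @param mask Optional logical vector of bins to exclude; by default bins
#'   within `mask_parS_kb` of a parS site plus zero-coverage reference bins
#'   are excluded.
#' @param mask_parS_kb Half-width of the parS exclusion zone in kb
#'   (default 20).
#' @return Non-negative score.
#' @export
gof_score <- function(sim, ref, mask = NULL, mask_parS_kb = 20) {
  if (length(sim$values) != length(ref$values) ||
      sim$bin_size != ref$bin_size)
    stop("profiles must share binning")
  if (is.null(mask)) {
    ctr <- bin_centers_signed(ref$genome, ref$bin_size)
    near_parS <- rep(FALSE, length(ctr))
    for (p in ref$genome$parS_bp)
      near_parS <- near_parS |
        circular_distance(ctr, p, ref$genome) <= mask_parS_kb * 1000
    mask <- near_parS | ref$values == 0
  }
  keep <- !mask
  if (!any(keep)) stop("all bins masked")
  a <- sim$values[keep]; b <- ref$values[keep]
  if (sum(a) <= 0 || sum(b) <= 0) stop("profiles have no mass in unmasked bins")
  a <- a / sum(a); b <- b / sum(b)
  sum((a - b)^2)
}

#' Sweep collision-engagement parameters against a reference occupancy
#'
#' Simulates the scenario on a grid of (tau_unload, tau_bypass) values
#' (infinite and near-zero entries embed the blocking-only, unloading-only
#' and bypassing-only models), scores each simulated SMC occupancy against
#' the reference with [gof_score()], and annotates the
#' `tau_bypass >= 2 * tau_unload` region where unloading is at least
#' two-fold faster than bypassing.
#'
#' @param scenario A scenario list (see [scenario()]).
#' @param tau_unload_grid,tau_bypass_grid Grids in seconds (may contain
#'   `Inf`).
#' @param ref_occupancy Reference `profile1d` occupancy.
#' @param n_cells Cells per simulation.
#' @param seed Integer seed (one stream per grid cell, derived).
#' @param sample_time Occupancy sample time (minutes; default the
#'   scenario's last sample).
#' @param bin_size Occupancy comparison bin size (default the reference's).
#' @return A `sweep_result` list: `grid` data.frame (tau_unload,
#'   tau_bypass, score, in_ratio_region), `best` rows, `best_in_ratio_region`
#'   flag.
#' @export
sweep_collision_params <- function(scenario, tau_unload_grid,
                                   tau_bypass_grid, ref_occupancy, n_cells,
                                   seed, sample_time = NULL,
                                   bin_size = NULL) {
  if (is.null(sample_time)) sample_time <- max(scenario$sample_times)
  if (is.null(bin_size)) bin_size <- ref_occupancy$bin_size
  cells <- expand.grid(tau_unload = tau_unload_grid,
                       tau_bypass = tau_bypass_grid)
  scores <- numeric(nrow(cells))
  for (g in seq_len(nrow(cells))) {
    prm <- scenario$smc_params
    prm$tau_unload <- cells$tau_unload[g]
    prm$tau_bypass <- cells$tau_bypass[g]
    prm$engagement_model <- "combined"
    sim <- simulate_joint(scenario$protocol, scenario$rep_params, prm,
                          scenario$genome, n_cells,
                          seed = seed + g, sample_times = sample_time,
                          constitutive_loading = scenario$constitutive_loading)
    occ <- compute_occupancy(sim$snapshots[[1]]$smcs, scenario$genome,
                             bin_size = bin_size)
    scores[g] <- gof_score(occ, ref_occupancy)
  }
  grid <- cbind(cells, score = scores,
                in_ratio_region = cells$tau_bypass >= 2 * cells$tau_unload)
  best <- grid[grid$score <= min(grid$score) + 1e-12, , drop = FALSE]
  structure(list(grid = grid, best = best,
                 best_in_ratio_region = all(best$in_ratio_region)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$grid, row.names = FALSE)
  cat("best cell(s):\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

# trailing-arc geometry: mean terminus-directed displacement binned on
# origin-directed displacement (an age proxy), plus the mean motor-to-fork
# trailing gap, over usable arc points
arc_curve <- function(points, load_pos, breaks) {
  sel <- points$bound & points$loaded_after_fork
  pts <- points[sel, , drop = FALSE]
  if (nrow(pts) < 3) return(NULL)
  d1 <- abs(pts$pos1 - load_pos)
  d2 <- abs(pts$pos2 - load_pos)
  lv <- seq_len(length(breaks) - 1)
  bin <- findInterval(d2, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin < length(breaks)
  fork <- attr(points, "fork_pos")
  gap <- if (is.null(fork)) NA_real_ else
    mean(abs(pts$pos1 - fork[sel])[ok])
  list(means = as.numeric(tapply(d1[ok], factor(bin[ok], levels = lv), mean)),
       counts = as.numeric(tapply(d1[ok], factor(bin[ok], levels = lv),
                                  length)),
       gap = gap)
}

#' Sweep the fork-memory duration against reference arc points
#'
#' Runs the reduced chase model ([simulate_arc2()]) over a grid of memory
#' durations and effective simulation times, scoring each cell by the
#' squared mismatch of the trailing-arc geometry -- the mean
#' terminus-directed displacement profiled against the origin-directed
#' displacement, which encodes both arc endpoints and arc angle -- against
#' the reference points. All grid cells share one RNG stream (common
#' random numbers). The best memory duration is reported with an
#' uncertainty band from the curvature of the score profile.
#'
#' @param t_memory_grid Memory durations in seconds.
#' @param time_grid Effective sample times in minutes.
#' @param ref_points Reference arc points: data.frame with `pos1`, `pos2`,
#'   `bound`, `loaded_after_fork` (as returned by [simulate_arc2()]).
#' @param load_pos Loading-site position, signed bp.
#' @param params,fork_speed,protocol,genome,n_pairs Passed to
#'   [simulate_arc2()].
#' @param seed Integer seed.
#' @param constitutive_loading Passed to [simulate_arc2()].
#' @return A `sweep_result` list: `grid` (t_memory, time, score), `best`,
#'   `best_t_memory`, `band` (half-width, seconds).
#' @export
sweep_fork_memory <- function(t_memory_grid, time_grid, ref_points, load_pos,
                              params, fork_speed, protocol, genome, n_pairs,
                              seed, constitutive_loading = FALSE) {
  sel <- ref_points$bound & ref_points$loaded_after_fork
  if (sum(sel) < 10) stop("reference contains no usable arc points")
  d2_ref <- abs(ref_points$pos2[sel] - load_pos)
  breaks <- seq(stats::quantile(d2_ref, 0.02), stats::quantile(d2_ref, 0.98),
                length.out = 16)
  ref <- arc_curve(ref_points, load_pos, breaks)
  scale2 <- mean(ref$means^2, na.rm = TRUE)
  grid <- expand.grid(t_memory = t_memory_grid, time = time_grid)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pts <- simulate_arc2(params, fork_speed, grid$t_memory[g], protocol,
                         genome, n_pairs, seed = seed,
                         sample_time = grid$time[g],
                         constitutive_loading = constitutive_loading)
    s <- arc_curve(pts, load_pos, breaks)
    if (is.null(s)) { scores[g] <- Inf; next }
    use <- !is.na(ref$means) & !is.na(s$means) &
      ref$counts >= 3 & s$counts >= 3
    # weight bins by their evidence so sparse arc ends do not dominate
    w <- pmin(ref$counts[use], s$counts[use])
    if (sum(use) < 4) { scores[g] <- Inf; next }
    sc <- sum(w * (s$means[use] - ref$means[use])^2) / sum(w) / scale2
    # the mean trailing gap behind the fork pins the memory extent and
    # breaks the memory/time degeneracy of the displacement curve alone
    if (is.finite(ref$gap) && is.finite(s$gap))
      sc <- sc + ((s$gap - ref$gap) / ref$gap)^2
    scores[g] <- sc
  }
  grid$score <- scores
  best <- grid[which.min(grid$score), , drop = FALSE]
  # profile over memory duration and a quadratic curvature band
  prof <- tapply(grid$score, grid$t_memory, min)
  tm <- as.numeric(names(prof))
  i <- which.min(prof)
  band <- NA_real_
  if (i > 1 && i < length(prof)) {
    fit <- stats::lm(prof[(i - 1):(i + 1)] ~ poly(tm[(i - 1):(i + 1)], 2,
                                                  raw = TRUE))
    a <- stats::coef(fit)[3]
    if (is.finite(a) && a > 0)
      band <- sqrt(max(prof[i], 1e-4) / a)
  }
  if (!is.finite(band)) band <- diff(range(tm)) / (length(tm) - 1) / 2
  structure(list(grid = grid, best = best, best_t_memory = best$t_memory,
                 band = band),
            class = "sweep_result")
}
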