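# Analytic (event-driven) fork trajectories.
#
# Within one protocol the fork speed schedule v(t) is globally piecewise
# constant (temperature shifts; v = 0 after HPUra). A fork created at time
# tau is then at arm progress F(t) - F(tau) with F(t) = integral of v, so
# fork positions, completion times and locus replication times (needed for
# the fork-memory factor) are all available in closed form per cell. The
# pre-history before T = 0 runs at the 42 degC speed so pre-existing forks
# are represented by a negative virtual initiation time.

make_speed_schedule <- function(protocol, rep_params, genome) {
  v42_bp <- rep_params$v42 * 1000 # bp/min
  # pre-history long enough for a full pre-existing arm
  t_start <- -(genome$length / 2) / v42_bp - 1
  ts <- protocol_temp_schedule(protocol, t_start)
  tk <- ts$time
  vk <- ifelse(ts$temp == 30, rep_params$v30, rep_params$v42) * 1000
  hp <- protocol_time_of(protocol, "ADD_HPURA")
  if (!is.na(hp)) {
    keep <- tk < hp
    tk <- c(tk[keep], hp)
    vk <- c(vk[keep], 0)
  }
  Fk <- c(0, cumsum(vk[-length(vk)] * diff(tk)))
  list(tk = tk, vk = vk, Fk = Fk)
}

sched_F <- function(sched, t) {
  i <- findInterval(t, sched$tk)
  i[i < 1L] <- 1L
  sched$Fk[i] + sched$vk[i] * (t - sched$tk[i])
}

# first time F reaches y (Inf if never within the schedule's final segment)
sched_Finv <- function(sched, y) {
  Fk <- sched$Fk; tk <- sched$tk; vk <- sched$vk
  j <- findInterval(y, Fk)
  j[j < 1L] <- 1L
  # step back over flat (v = 0) segments reached exactly
  while (any(bad <- vk[j] == 0 & j > 1L & Fk[j] <= y & abs(Fk[j] - y) < 1e-9))
    j[bad] <- j[bad] - 1L
  out <- tk[j] + (y - Fk[j]) / vk[j]
  out[vk[j] == 0 & y > Fk[j] + 1e-9] <- Inf
  out[vk[j] == 0 & abs(y - Fk[j]) <= 1e-9] <- tk[j][vk[j] == 0 & abs(y - Fk[j]) <= 1e-9]
  out
}

# permissive (30 degC) windows within [0, horizon]
permissive_windows <- function(protocol, horizon) {
  ts <- protocol_temp_schedule(protocol, -1)
  brk <- c(ts$time, horizon)
  out <- NULL
  for (i in seq_len(nrow(ts))) {
    a <- max(ts$time[i], 0); b <- min(brk[i + 1L], horizon)
    if (ts$temp[i] == 30 && b > a) out <- rbind(out, c(a, b))
  }
  out
}

# map an exponential clock of permissive time to an absolute initiation time
init_time_from_clock <- function(E, windows) {
  if (is.null(windows)) return(rep(Inf, length(E)))
  durs <- windows[, 2] - windows[, 1]
  cum <- c(0, cumsum(durs))
  out <- rep(Inf, length(E))
  for (i in seq_len(nrow(windows))) {
    inwin <- E > cum[i] & E <= cum[i + 1L]
    out[inwin] <- windows[i, 1] + (E[inwin] - cum[i])
  }
  out
}

# Draw per-cell fork trajectories. Uses the current RNG stream.
make_fork_trajectories <- function(protocol, rep_params, genome, n_cells,
                                   horizon) {
  sched <- make_speed_schedule(protocol, rep_params, genome)
  half <- genome$length / 2
  pre <- stats::runif(n_cells) < rep_params$f_pre
  u <- stats::runif(n_cells)
  E <- stats::rexp(n_cells, rate = 1 / rep_params$t_init_mean)
  win <- permissive_windows(protocol, horizon)
  tau <- init_time_from_clock(E, win)
  # pre-existing forks: virtual init time so that progress at t=0 is u*half
  F0 <- sched_F(sched, 0)
  tau[pre] <- sched_Finv(sched, F0 - u[pre] * half)
  Ftau <- ifelse(is.finite(tau), sched_F(sched, tau), Inf)
  t_complete <- ifelse(is.finite(tau), sched_Finv(sched, Ftau + half), Inf)
  # spontaneous stalls: exponential in moving time, which equals wall time
  # from tau until HPUra flattens the schedule or the fork completes
  stall <- function() {
    if (rep_params$p_stall <= 0) return(rep(Inf, n_cells))
    W <- stats::rexp(n_cells, rate = rep_params$p_stall)
    ts <- tau + W
    ts[!is.finite(tau)] <- Inf
    # no stall once frozen (v=0) or completed: freezing makes it moot anyway
    ifelse(ts < t_complete, ts, Inf)
  }
  t_stall_L <- stall()
  t_stall_R <- stall()
  list(sched = sched, genome = genome, n_cells = n_cells,
       tau = tau, Ftau = Ftau, pre = pre,
       t_stall_L = t_stall_L, t_stall_R = t_stall_R,
       half = half)
}

# absolute arm progress (bp >= 0) of each fork at time t; 0 if no fork yet
fork_progress <- function(traj, t, t_stall) {
  p <- sched_F(traj$sched, pmin(t, t_stall)) - traj$Ftau
  p[!is.finite(traj$tau) | t < traj$tau] <- 0
  pmin(pmax(p, 0), traj$half)
}

# per-cell fork state at time t
fork_state_at <- function(traj, t) {
  pl <- fork_progress(traj, t, traj$t_stall_L)
  pr <- fork_progress(traj, t, traj$t_stall_R)
  v <- traj$sched$vk[pmax(findInterval(t, traj$sched$tk), 1L)]
  list(prog_L = pl, prog_R = pr,
       exists_L = is.finite(traj$tau) & t >= traj$tau & pl < traj$half,
       exists_R = is.finite(traj$tau) & t >= traj$tau & pr < traj$half,
       moving_L = v > 0 & is.finite(traj$tau) & t >= traj$tau &
         t < traj$t_stall_L & pl < traj$half,
       moving_R = v > 0 & is.finite(traj$tau) & t >= traj$tau &
         t < traj$t_stall_R & pr < traj$half)
}

# time since the locus at absolute arm position x (bp) was replicated in
# each cell; NA if not replicated (by this round) at time t
replication_age <- function(traj, cell, x_abs, arm_is_left, t) {
  t_stall <- ifelse(arm_is_left, traj$t_stall_L[cell], traj$t_stall_R[cell])
  prog <- sched_F(traj$sched, pmin(t, t_stall)) - traj$Ftau[cell]
  prog[!is.finite(traj$tau[cell]) | t < traj$tau[cell]] <- 0
  prog <- pmin(pmax(prog, 0), traj$half)
  t_pass <- sched_Finv(traj$sched, traj$Ftau[cell] + x_abs)
  age <- t - t_pass
  age[x_abs > prog + 1e-9] <- NA_real_
  age
}

# fork snapshot in the same schema as init_population()/step_forks()
snapshot_forks <- function(traj, t) {
  st <- fork_state_at(traj, t)
  data.frame(cell = seq_len(traj$n_cells),
             initiated = is.finite(traj$tau) & t >= traj$tau,
             left_pos = -st$prog_L,
             right_pos = st$prog_R,
             left_stalled = t >= traj$t_stall_L,
             right_stalled = t >= traj$t_stall_R,
             completed = st$prog_L >= traj$half & st$prog_R >= traj$half &
               is.finite(traj$tau) & t >= traj$tau)
}
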