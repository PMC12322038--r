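# Vectorized ensemble engine: all complexes of all cells are simulated as
# flat parallel vectors, one global clock in seconds.

#' Initialize an (unbound) SMC ensemble state
#'
#' One slot per complex per cell (`n_cells * n_smc` slots). Motor 1
#' translocates toward decreasing signed coordinates, motor 2 toward
#' increasing; both stop at the terminus (+/- length/2).
#'
#' @param n_cells Number of cells.
#' @param params An [smc_params()].
#' @return A list of parallel vectors (class `smc_state`).
#' @export
smc_ensemble_init <- function(n_cells, params) {
  N <- n_cells * params$n_smc
  structure(list(
    n_cells = n_cells,
    cell = rep(seq_len(n_cells), each = params$n_smc),
    bound = logical(N),
    load_pos = numeric(N), load_time = rep(NA_real_, N),
    pos1 = numeric(N), pos2 = numeric(N),
    blk1 = logical(N), blk2 = logical(N),
    bfork1 = rep(NA_integer_, N), bfork2 = rep(NA_integer_, N),
    ev_t1 = rep(Inf, N), ev_t2 = rep(Inf, N),
    ev_o1 = integer(N), ev_o2 = integer(N), # 0 none, 1 unload, 2 bypass
    dissoc_time = rep(Inf, N),
    n_byp1 = integer(N), n_byp2 = integer(N)),
    class = "smc_state")
}

#' Fork barrier view of a cell population
#'
#' Converts a fork snapshot data.frame (schema of [init_population()]) into
#' the per-cell barrier list consumed by [step_smcs()]: fork positions and
#' whether each fork still exists (initiated and short of the terminus).
#'
#' @param forks Fork snapshot data.frame.
#' @param genome A [genome_spec()].
#' @return List with `left_pos`, `right_pos`, `exists_L`, `exists_R`.
#' @export
fork_barriers <- function(forks, genome) {
  half <- genome$length / 2
  list(left_pos = forks$left_pos, right_pos = forks$right_pos,
       exists_L = forks$initiated & forks$left_pos > -half,
       exists_R = forks$initiated & forks$right_pos < half)
}

barriers_at <- function(traj, t_min) {
  st <- fork_state_at(traj, t_min)
  list(left_pos = -st$prog_L, right_pos = st$prog_R,
       exists_L = st$exists_L, exists_R = st$exists_R)
}

# age_fun(cells, x_abs, arm_is_left, t_min) -> minutes since replication (NA
# if unreplicated); default: nothing is ever replicated.
no_replication_age <- function(cells, x_abs, arm_is_left, t_min) {
  rep(NA_real_, length(cells))
}

#' Advance the SMC ensemble by one time step
#'
#' One step of the loop-extrusion engine: unblocked motors advance by
#' `motor_speed * dt` (direction-dependent, fork-memory-scaled); blocked
#' motors sit at, and are carried with, the blocking fork (a head-on-blocked
#' motor against a moving fork is pushed backward at fork speed); scheduled
#' unloads remove the whole complex and scheduled bypasses place the motor
#' just past the fork; encounters are detected by interval crossing so
#' motors cannot tunnel through a fork; bound complexes dissociate
#' spontaneously at rate `1/tau_dissoc`; unbound pool slots reload at
#' `load_rate` while loading is active.
#'
#' @param state An `smc_state` from [smc_ensemble_init()].
#' @param barriers0,barriers1 Fork barrier lists (see [fork_barriers()]) at
#'   the start and end of the step.
#' @param age_fun Function `(cells, x_abs, arm_is_left, t_min)` returning
#'   minutes since replication of the locus at arm position `x_abs` in each
#'   cell (NA = unreplicated); used for the fork-memory factor.
#' @param params An [smc_params()].
#' @param genome A [genome_spec()].
#' @param t_s Step start time in seconds.
#' @param dt Step size in seconds (must keep motor displacement below a few
#'   kb; default engine uses 1 s).
#' @param loading_active Logical: is SMC loading currently possible?
#' @return List with the updated `state` and `unbound`, a data.frame of
#'   complexes that left the chromosome during the step (columns `cell`,
#'   `time`, `reason`, `lifetime`).
#' @export
step_smcs <- function(state, barriers0, barriers1, age_fun = no_replication_age,
                      params, genome, t_s, dt = 1, loading_active = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt * max(params$v_to_ter, params$v_to_ori) * 1000 / 60 > 5000)
    stop("dt too large for stable encounter detection")
  half <- genome$length / 2
  t1 <- t_s + dt
  t_min0 <- t_s / 60
  ub_cell <- integer(); ub_reason <- character(); ub_life <- numeric()
  unbind <- function(i, reason) {
    if (!length(i)) return(invisible())
    ub_cell <<- c(ub_cell, state$cell[i])
    ub_reason <<- c(ub_reason, rep(reason, length(i)))
    ub_life <<- c(ub_life, t1 - state$load_time[i])
    state$bound[i] <<- FALSE
    state$blk1[i] <<- FALSE; state$blk2[i] <<- FALSE
    state$ev_t1[i] <<- Inf; state$ev_t2[i] <<- Inf
    state$ev_o1[i] <<- 0L; state$ev_o2[i] <<- 0L
    state$dissoc_time[i] <<- Inf
  }

  # spontaneous dissociation (applies to blocked complexes too)
  unbind(which(state$bound & state$dissoc_time <= t1), "dissoc")

  # fid may be scalar (encounter scan) or per-motor vector (blocked carry)
  fork_pos_at <- function(b, fid, cells) {
    out <- b$right_pos[cells]
    left <- rep_len(fid == 1L, length(cells))
    out[left] <- b$left_pos[cells][left]
    out
  }
  fork_exists_at <- function(b, fid, cells) {
    out <- b$exists_R[cells]
    left <- rep_len(fid == 1L, length(cells))
    out[left] <- b$exists_L[cells][left]
    out
  }

  # blocked motors: releases, scheduled outcomes, carriage with the fork
  for (k in 1:2) {
    blk <- paste0("blk", k); posk <- paste0("pos", k)
    bfk <- paste0("bfork", k); evt <- paste0("ev_t", k); evo <- paste0("ev_o", k)
    nbk <- paste0("n_byp", k)
    d <- if (k == 1L) -1 else 1
    i <- which(state$bound & state[[blk]])
    if (!length(i)) next
    cells <- state$cell[i]
    fid <- state[[bfk]][i]
    fp1 <- fork_pos_at(barriers1, fid, cells)
    alive <- fork_exists_at(barriers1, fid, cells)
    # fork vanished (completed): release the motor unblocked, clocks discarded
    rel <- i[!alive]
    if (length(rel)) {
      state[[posk]][rel] <- fp1[!alive]
      state[[blk]][rel] <- FALSE
      state[[evt]][rel] <- Inf; state[[evo]][rel] <- 0L
      state[[bfk]][rel] <- NA_integer_
    }
    i <- i[alive]; fp1 <- fp1[alive]
    if (!length(i)) next
    due <- state[[evt]][i] <= t1
    out <- state[[evo]][i]
    # unloading removes the whole complex
    unbind(i[due & out == 1L], "unload")
    still <- state$bound[i]
    # bypass: place the motor one offset past the fork, resume translocation
    byp <- due & out == 2L & still
    if (any(byp)) {
      j <- i[byp]
      state[[posk]][j] <- pmin(pmax(fp1[byp] + d * params$bypass_offset,
                                    -half), half)
      state[[blk]][j] <- FALSE
      state[[evt]][j] <- Inf; state[[evo]][j] <- 0L
      state[[bfk]][j] <- NA_integer_
      state[[nbk]][j] <- state[[nbk]][j] + 1L
    }
    # still blocked: carried with (possibly moving) fork
    carry <- !due & still
    state[[posk]][i[carry]] <- fp1[carry]
  }

  # unblocked motors: memory-scaled advance, then encounter detection
  for (k in 1:2) {
    blk <- paste0("blk", k); posk <- paste0("pos", k)
    bfk <- paste0("bfork", k); evt <- paste0("ev_t", k); evo <- paste0("ev_o", k)
    d <- if (k == 1L) -1 else 1
    i <- which(state$bound & !state[[blk]])
    if (!length(i)) next
    cells <- state$cell[i]
    p0 <- state[[posk]][i]
    arm_left <- p0 < 0 | (p0 == 0 & d < 0)
    age_min <- age_fun(cells, abs(p0), arm_left, t_min0)
    v <- motor_speed(p0, d, age_min * 60, params) # kb/min
    prop <- pmin(pmax(p0 + d * v * 1000 / 60 * dt, -half), half)
    # left fork then right fork; one crossing per step at engine dt
    hit <- rep(NA_integer_, length(i))
    hit_pos <- numeric(length(i))
    for (fid in 1:2) {
      f0 <- fork_pos_at(barriers0, fid, cells)
      f1 <- fork_pos_at(barriers1, fid, cells)
      ex <- fork_exists_at(barriers0, fid, cells) &
        fork_exists_at(barriers1, fid, cells)
      d0 <- p0 - f0; d1 <- prop - f1
      crossed <- ex & is.na(hit) & (d0 * d1 < 0 | (d0 != 0 & d1 == 0))
      hit[crossed] <- fid
      hit_pos[crossed] <- f1[crossed]
    }
    enc <- !is.na(hit)
    state[[posk]][i[!enc]] <- prop[!enc]
    if (any(enc)) {
      j <- i[enc]
      state[[posk]][j] <- hit_pos[enc]
      state[[blk]][j] <- TRUE
      state[[bfk]][j] <- hit[enc]
      rb <- resolve_block(length(j), params)
      state[[evt]][j] <- t1 + rb$wait
      state[[evo]][j] <- ifelse(rb$outcome == "UNLOAD", 1L,
                                ifelse(rb$outcome == "BYPASS", 2L, 0L))
    }
  }

  # loading of unbound pool slots
  if (loading_active) {
    p_load <- 1 - exp(-params$load_rate * dt)
    fire <- which(!state$bound &
                    stats::runif(length(state$bound)) < p_load)
    if (length(fire)) {
      lp <- sample_load_positions(length(fire), genome, params)
      state$bound[fire] <- TRUE
      state$load_pos[fire] <- lp
      state$pos1[fire] <- lp; state$pos2[fire] <- lp
      state$load_time[fire] <- t1
      state$dissoc_time[fire] <- t1 +
        stats::rexp(length(fire), 1 / params$tau_dissoc)
      state$n_byp1[fire] <- 0L; state$n_byp2[fire] <- 0L
    }
  }

  list(state = state,
       unbound = data.frame(cell = ub_cell, time = rep(t1, length(ub_cell)),
                            reason = ub_reason, lifetime = ub_life))
}

smc_snapshot <- function(state, t_min) {
  i <- which(state$bound)
  data.frame(cell = state$cell[i], slot = i,
             load_pos = state$load_pos[i],
             pos1 = state$pos1[i], pos2 = state$pos2[i],
             blocked1 = state$blk1[i], blocked2 = state$blk2[i],
             load_time = state$load_time[i] / 60,
             n_byp1 = state$n_byp1[i], n_byp2 = state$n_byp2[i],
             time = rep(t_min, length(i)))
}

#' Joint replisome + SMC ensemble simulation
#'
#' Simulates a cell population through a protocol: fork trajectories follow
#' the replisome model (exactly, via the piecewise-linear speed schedule,
#' so locus replication ages for the fork-memory factor are closed-form)
#' and the SMC ensemble is stepped at `dt` seconds against those forks.
#' Emits, per sample time, all bound anchor pairs and the fork positions.
#'
#' @param protocol A [protocol()].
#' @param rep_params A [replisome_params()].
#' @param params An [smc_params()].
#' @param genome A [genome_spec()].
#' @param n_cells Number of cells.
#' @param seed Integer RNG seed.
#' @param sample_times Sampling times in minutes (default: protocol SAMPLE
#'   events).
#' @param dt SMC engine step, seconds (default 1).
#' @param constitutive_loading If TRUE, SMC loading is active from T = 0
#'   (no IPTG gating).
#' @return A list of class `smc_ensemble`: `snapshots` (per sample time:
#'   `time`, `smcs` anchor-pair data.frame, `forks` fork snapshot),
#'   `unbound` (log of unloading/dissociation events), and the inputs.
#' @export
simulate_joint <- function(protocol, rep_params, params, genome, n_cells,
                           seed = NULL, sample_times = NULL, dt = 1,
                           constitutive_loading = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_times)) sample_times <- protocol_samples(protocol)
  if (!length(sample_times)) stop("no sample times")
  sample_times <- sort(sample_times)
  horizon <- max(sample_times)
  traj <- make_fork_trajectories(protocol, rep_params, genome, n_cells,
                                 horizon)
  state <- smc_ensemble_init(n_cells, params)
  t_load <- loading_start_time(protocol, constitutive_loading,
                               params$loading_lag)
  age_fun <- function(cells, x_abs, arm_is_left, t_min)
    replication_age(traj, cells, x_abs, arm_is_left, t_min)
  nstep <- ceiling(horizon * 60 / dt)
  snaps <- vector("list", length(sample_times))
  names(snaps) <- as.character(sample_times)
  unb <- vector("list", nstep)
  k <- 1L
  while (k <= length(sample_times) && sample_times[k] <= 1e-9) {
    snaps[[k]] <- list(time = sample_times[k],
                       smcs = smc_snapshot(state, 0),
                       forks = snapshot_forks(traj, sample_times[k]))
    k <- k + 1L
  }
  b1 <- barriers_at(traj, 0)
  for (s in seq_len(nstep)) {
    t_s <- (s - 1) * dt
    t1_min <- (t_s + dt) / 60
    b0 <- b1
    b1 <- barriers_at(traj, t1_min)
    res <- step_smcs(state, b0, b1, age_fun, params, genome, t_s, dt,
                     loading_active = t_s / 60 >= t_load)
    state <- res$state
    if (nrow(res$unbound)) unb[[s]] <- res$unbound
    while (k <= length(sample_times) && sample_times[k] <= t1_min + 1e-9) {
      snaps[[k]] <- list(time = sample_times[k],
                         smcs = smc_snapshot(state, t1_min),
                         forks = snapshot_forks(traj, sample_times[k]))
      k <- k + 1L
    }
  }
  structure(list(snapshots = snaps, unbound = do.call(rbind, unb[!vapply(unb, is.null, logical(1))]),
                 sample_times = sample_times, n_cells = n_cells,
                 params = params, rep_params = rep_params, genome = genome),
            class = "smc_ensemble")
}

#' Stand-alone reduced model of SMC motors chasing a moving fork
#'
#' The reduced model behind the trailing-arc ("arc 2") analysis: independent
#' motor pairs load at a single parS site at times spread over the loading
#' window and translocate with fork-memory-scaled speeds against a single
#' fork moving at constant speed down the parS arm. No SMC-SMC
#' interactions, no blocking/pushing, and no unloading at the fork: the
#' chasing motor simply cannot pass the fork (with memory on it
#' asymptotically trails it; with `t_memory = 0` it reaches and tracks it).
#'
#' @param params An [smc_params()] (speeds, residence, loading lag).
#' @param fork_speed Constant fork speed, kb/min.
#' @param t_memory Fork-memory duration, seconds (overrides `params`).
#' @param protocol A [protocol()] (initiation window, IPTG, samples).
#' @param genome A [genome_spec()] whose first parS site is the loading site.
#' @param n_pairs Number of independent motor pairs.
#' @param seed Integer RNG seed.
#' @param sample_time Minutes; default the last protocol SAMPLE event.
#' @param constitutive_loading If TRUE loading starts at T = 0.
#' @param t_init_mean Mean replisome loading delay at initiation, minutes
#'   (truncated to the permissive window; default 5).
#' @param dt Step in seconds (default 1).
#' @return A data.frame of final motor positions per pair: `load_time`,
#'   `pos1` (terminus-directed, i.e. chasing, motor), `pos2`
#'   (origin-directed motor), `bound` at the sample time,
#'   `loaded_after_fork` (loaded after the fork passed parS),
#'   `fork_init_time` and `parS_passage_time` (per-pair ground truth,
#'   minutes). The per-pair fork positions at the sample time and the parS
#'   position are attached as attributes `fork_pos` and `parS`.
#' @export
simulate_arc2 <- function(params, fork_speed, t_memory, protocol, genome,
                          n_pairs, seed = NULL, sample_time = NULL,
                          constitutive_loading = FALSE, t_init_mean = 5,
                          dt = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_time)) {
    st <- protocol_samples(protocol)
    if (!length(st)) stop("no sample time")
    sample_time <- max(st)
  }
  if (!length(genome$parS_bp)) stop("genome has no parS site")
  parS <- genome$parS_bp[1]
  if (parS >= 0) stop("reduced chase model expects a left-arm parS site")
  half <- genome$length / 2
  win <- permissive_windows(protocol, sample_time)
  t0_fork <- if (is.null(win)) 0 else win[1, 1]
  # stochastic replisome loading delay at initiation (exponential truncated
  # to the permissive window: only initiating cells contribute a fork)
  if (is.null(win)) {
    tau <- t0_fork + stats::rexp(n_pairs, 1 / t_init_mean)
  } else {
    D <- win[1, 2] - win[1, 1]
    u <- stats::runif(n_pairs) * (1 - exp(-D / t_init_mean))
    tau <- t0_fork - t_init_mean * log(1 - u)
  }
  load_start <- max(loading_start_time(protocol, constitutive_loading,
                                       params$loading_lag), 0)
  s_load <- stats::runif(n_pairs, load_start, sample_time)
  life <- stats::rexp(n_pairs, 1 / params$tau_dissoc) / 60
  t_end <- pmin(sample_time, s_load + life)
  fork_at <- function(t) pmin(pmax((t - tau) * fork_speed * 1000, 0), half)
  p1 <- rep(parS, n_pairs) # terminus-directed (chasing) motor, dir -1
  p2 <- rep(parS, n_pairs) # origin-directed motor, dir +1
  mem <- function(p, t, idx) {
    # memory factor on the left (parS) arm; fork passage time tau + |p|/v_f
    x <- abs(p)
    prog <- pmin(pmax((t - tau[idx]) * fork_speed * 1000, 0), half)
    age_s <- (t - (tau[idx] + x / (fork_speed * 1000))) * 60
    m <- memory_factor(age_s, t_memory)
    m[p > 0] <- 1 # right arm: untouched by the single modelled fork
    m[x > prog] <- 1 # unreplicated: no memory
    m
  }
  nstep <- ceiling(sample_time * 60 / dt)
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt / 60
    t1 <- s * dt / 60
    act <- which(s_load <= t & t_end > t)
    if (!length(act)) next
    fp0 <- -pmin(pmax((t - tau[act]) * fork_speed * 1000, 0), half)
    fp1 <- -pmin(pmax((t1 - tau[act]) * fork_speed * 1000, 0), half)
    # chasing motor: full ter-ward speed scaled by memory, cannot pass fork
    v1 <- params$v_to_ter * mem(p1[act], t, act)
    new1 <- p1[act] - v1 * 1000 / 60 * dt
    behind <- p1[act] >= fp0
    new1[behind] <- pmax(new1[behind], fp1[behind])
    p1[act] <- pmax(new1, -half)
    # origin-directed motor: direction-dependent base speed; unaffected by
    # memory while heading away from the fork
    v2 <- motor_speed(p2[act], +1, NA, params)
    p2[act] <- pmin(p2[act] + v2 * 1000 / 60 * dt, half)
  }
  passage <- tau + abs(parS) / (fork_speed * 1000)
  out <- data.frame(load_time = s_load, pos1 = p1, pos2 = p2,
                    bound = t_end >= sample_time,
                    loaded_after_fork = s_load >= passage,
                    fork_init_time = tau, parS_passage_time = passage)
  attr(out, "parS") <- parS
  attr(out, "fork_pos") <- -fork_at(sample_time)
  attr(out, "sample_time") <- sample_time
  out
}
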