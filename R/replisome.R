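#' Replisome model parameters
#'
#' Five-parameter stochastic model of synchronized replication: a fraction
#' of cells escapes the G1 arrest and carries a pre-existing fork pair at
#' T = 0; the remaining cells initiate with an exponential delay while the
#' temperature is permissive; forks elongate at a temperature-specific
#' speed, are frozen in place by HPUra, and stall spontaneously and
#' irreversibly at a small per-minute rate.
#'
#' @param f_pre Fraction of cells with a pre-existing fork pair at T = 0
#'   (default 0.18).
#' @param t_init_mean Mean of the exponential replisome-loading delay after
#'   initiation becomes allowed, in minutes (default 5; with the standard
#'   15-min permissive window this gives an initiation fraction of
#'   `1 - exp(-15/5) ~ 0.95`).
#' @param v30 Elongation speed at 30 degC, kb/min (default 40).
#' @param v42 Elongation speed at 42 degC, kb/min (default 66).
#' @param p_stall Per-fork per-minute probability of irreversible
#'   spontaneous stalling (default 0.004).
#' @return An object of class `replisome_params`.
#' @export
replisome_params <- function(f_pre = 0.18, t_init_mean = 5, v30 = 40,
                             v42 = 66, p_stall = 0.004) {
  stopifnot(f_pre >= 0, f_pre <= 1, t_init_mean > 0, v30 > 0, v42 > 0,
            p_stall >= 0, p_stall < 1)
  structure(list(f_pre = f_pre, t_init_mean = t_init_mean, v30 = v30,
                 v42 = v42, p_stall = p_stall),
            class = "replisome_params")
}

fork_speed_at_temp <- function(params, temperature) {
  if (temperature == 30) params$v30 else params$v42
}

#' Initialize a cell population at T = 0
#'
#' A fraction `f_pre` of cells carries a pre-existing fork pair whose
#' arm-progress fraction is uniform on (0, 1), equal on both arms; the rest
#' are unreplicated. Per-cell copy number is represented on a single-sister
#' coordinate: the replicated set is `[left_pos, right_pos]` (through the
#' origin).
#'
#' @param params A [replisome_params()].
#' @param genome A [genome_spec()].
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer RNG seed.
#' @return A data.frame with one row per cell and columns `cell`,
#'   `initiated`, `left_pos`, `right_pos`, `left_stalled`, `right_stalled`,
#'   `completed`.
#' @export
init_population <- function(params, genome, n_cells, seed = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  pre <- stats::runif(n_cells) < params$f_pre
  u <- stats::runif(n_cells)
  half <- genome$length / 2
  cells <- data.frame(
    cell = seq_len(n_cells),
    initiated = pre,
    left_pos = ifelse(pre, -u * half, 0),
    right_pos = ifelse(pre, u * half, 0),
    left_stalled = FALSE,
    right_stalled = FALSE,
    completed = FALSE)
  cells
}

#' Advance replication forks by one time step
#'
#' Non-initiated cells initiate with exponential delay (mean `t_init_mean`)
#' while the environment allows initiation; active, unstalled forks advance
#' by `speed(temperature) * dt`, clipped at the terminus; HPUra
#' (`env$forks_stalled`) freezes all forks in place (forks persist, no
#' degradation); each active fork independently stalls irreversibly with
#' probability `p_stall * dt`. Replication completes when both forks reach
#' the terminus.
#'
#' @param cells Population data.frame as returned by [init_population()].
#' @param env Environment list from [env_at()].
#' @param params A [replisome_params()].
#' @param genome A [genome_spec()].
#' @param dt Time step in minutes (> 0, small relative to `1/p_stall`).
#' @return Updated population data.frame.
#' @export
step_forks <- function(cells, env, params, genome, dt) {
  if (dt <= 0) stop("dt must be > 0")
  n <- nrow(cells)
  half <- genome$length / 2
  # initiation; a cell initiating within the step starts at a uniform time
  # inside it (keeps fork positions off the dt lattice)
  frac <- rep(1, n)
  if (env$initiation_allowed) {
    p_init <- 1 - exp(-dt / params$t_init_mean)
    fire <- !cells$initiated & stats::runif(n) < p_init
    cells$initiated[fire] <- TRUE
    frac[fire] <- stats::runif(sum(fire))
  }
  if (!env$forks_stalled) {
    v_bp <- fork_speed_at_temp(params, env$temperature) * 1000 * dt * frac
    act_l <- cells$initiated & !cells$completed & !cells$left_stalled
    act_r <- cells$initiated & !cells$completed & !cells$right_stalled
    cells$left_pos[act_l] <- pmax(cells$left_pos[act_l] - v_bp[act_l], -half)
    cells$right_pos[act_r] <- pmin(cells$right_pos[act_r] + v_bp[act_r], half)
    # spontaneous irreversible stalling of active forks
    if (params$p_stall > 0) {
      p <- params$p_stall * dt
      cells$left_stalled[act_l & stats::runif(n) < p] <- TRUE
      cells$right_stalled[act_r & stats::runif(n) < p] <- TRUE
    }
    cells$completed <- cells$completed |
      (cells$left_pos <= -half & cells$right_pos >= half)
  }
  cells
}

#' Simulate a replication time course
#'
#' Steps a population through a protocol and returns fork snapshots at the
#' requested sample times. Snapshots feed [compute_mfa()].
#'
#' @param protocol A [protocol()].
#' @param params A [replisome_params()].
#' @param genome A [genome_spec()].
#' @param n_cells Number of cells.
#' @param seed Integer RNG seed.
#' @param sample_times Times (minutes) at which to snapshot; defaults to the
#'   protocol's SAMPLE events.
#' @param dt Step size in minutes (default 0.25).
#' @return A named list (one element per sample time, names are the times)
#'   of population data.frames.
#' @export
simulate_replication <- function(protocol, params, genome, n_cells,
                                 seed = NULL, sample_times = NULL,
                                 dt = 0.25) {
  if (is.null(sample_times)) sample_times <- protocol_samples(protocol)
  if (!length(sample_times)) stop("no sample times")
  sample_times <- sort(sample_times)
  cells <- init_population(params, genome, n_cells, seed)
  out <- vector("list", length(sample_times))
  names(out) <- as.character(sample_times)
  t_end <- max(sample_times)
  # chop time at protocol breakpoints so the environment is constant per step
  brk <- sort(unique(c(0, protocol$events$time, sample_times, t_end)))
  brk <- brk[brk >= 0 & brk <= t_end]
  k <- 1L
  emit <- function(t) {
    while (k <= length(sample_times) && sample_times[k] <= t + 1e-9) {
      out[[k]] <<- cells
      k <<- k + 1L
    }
  }
  emit(0)
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    env <- env_at(protocol, t0)
    nstep <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nstep
    for (s in seq_len(nstep))
      cells <- step_forks(cells, env, params, genome, h)
    emit(t1)
  }
  out
}
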