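#' SMC loop-extrusion parameters
#'
#' Parameters of the two-motor loop-extrusion model. Each complex loads at
#' a single site (preferentially parS) and its two motors translocate away
#' from the loading site in opposite directions. On meeting a replisome a
#' motor is blocked and then, depending on the engagement model, unloads
#' (whole complex removed) or bypasses (motor placed just past the fork)
#' after competing exponential waiting times; motors traversing recently
#' replicated DNA are slowed by the fork-memory factor.
#'
#' @param n_smc Target number of complexes per chromosome (default 40).
#' @param v_to_ter Motor speed toward the terminus, kb/min (default 71.5).
#' @param v_to_ori Motor speed toward the origin, kb/min (default 49; set
#'   equal to `v_to_ter` for origin-proximal parS scenarios).
#' @param tau_dissoc Mean spontaneous residence time, seconds (default 1200).
#' @param parS_weight Relative loading propensity per parS site (default 1).
#' @param background_weight Loading propensity per bp of non-parS DNA
#'   (default 2.5e-8; with one parS site this puts >90% of loads at parS).
#' @param tau_unload Mean time from block to unloading, seconds (default 30).
#' @param tau_bypass Mean time from block to bypassing, seconds (default 120).
#' @param engagement_model One of `"combined"`, `"bypass_only"`,
#'   `"block_only"`, `"unload_only"`.
#' @param t_memory Fork-memory duration in seconds (default 700; 0 disables
#'   the memory slowdown).
#' @param load_rate Per-complex loading rate for unbound pool members,
#'   per second (default 1/60).
#' @param loading_lag Dead time between IPTG addition and loading onset,
#'   minutes (default 5).
#' @param bypass_offset Distance past the fork at which a bypassing motor
#'   resumes, bp (default 1000, one lattice bin).
#' @return An object of class `smc_params`.
#' @export
smc_params <- function(n_smc = 40, v_to_ter = 71.5, v_to_ori = 49,
                       tau_dissoc = 1200, parS_weight = 1,
                       background_weight = 2.5e-8, tau_unload = 30,
                       tau_bypass = 120,
                       engagement_model = c("combined", "bypass_only",
                                            "block_only", "unload_only"),
                       t_memory = 700, load_rate = 1 / 60,
                       loading_lag = 5, bypass_offset = 1000) {
  engagement_model <- match.arg(engagement_model)
  stopifnot(n_smc >= 1, v_to_ter > 0, v_to_ori > 0, tau_dissoc > 0,
            parS_weight >= 0, background_weight >= 0,
            tau_unload > 0, tau_bypass > 0, t_memory >= 0,
            load_rate > 0, bypass_offset > 0)
  structure(list(n_smc = as.integer(n_smc), v_to_ter = v_to_ter,
                 v_to_ori = v_to_ori, tau_dissoc = tau_dissoc,
                 parS_weight = parS_weight,
                 background_weight = background_weight,
                 tau_unload = tau_unload, tau_bypass = tau_bypass,
                 engagement_model = engagement_model, t_memory = t_memory,
                 load_rate = load_rate, loading_lag = loading_lag,
                 bypass_offset = bypass_offset),
            class = "smc_params")
}

# effective (tau_unload, tau_bypass) embedding of the four engagement models
effective_taus <- function(params) {
  switch(params$engagement_model,
         combined = c(params$tau_unload, params$tau_bypass),
         block_only = c(Inf, Inf),
         unload_only = c(params$tau_unload, Inf),
         bypass_only = c(Inf, params$tau_bypass))
}

#' Fork-memory slowdown factor
#'
#' Linear ramp in time since replication: a locus replicated `age` seconds
#' ago scales motor speed by `clip(age / t_memory, 0, 1)`. Unreplicated (or
#' never-replicated-this-round) loci carry no memory (`age = NA` maps to 1),
#' and a locus exactly at the fork (`age = 0`) stops the motor. For a fork
#' moving at constant speed `v_f` this time formulation equals a distance
#' ramp over `t_memory * v_f` behind the fork.
#'
#' @param age_s Seconds since replication of the locus (NA = unreplicated).
#' @param t_memory Memory duration in seconds; 0 disables (factor 1).
#' @return Factor(s) in \[0, 1\].
#' @export
memory_factor <- function(age_s, t_memory) {
  if (t_memory <= 0) return(rep(1, length(age_s)))
  m <- pmin(pmax(age_s / t_memory, 0), 1)
  m[is.na(age_s)] <- 1
  m
}

#' Instantaneous motor speed
#'
#' Base speed by current travel direction (toward terminus or toward
#' origin), scaled by the fork-memory factor at the motor's position.
#' The memory slowdown applies only to terminus-directed motors -- those
#' translocating in the direction of fork movement, into ever more
#' recently replicated DNA. An origin-directed motor moves away from the
#' fork onto older DNA and out of the affected zone, and the upward tilt
#' of the trailing arc (terminus-directed much slower than
#' origin-directed) requires it to be essentially unhindered.
#'
#' @param pos Signed bp position(s) of the motor.
#' @param dir Travel direction along the signed coordinate (-1 or +1).
#' @param age_s Seconds since the motor's locus was replicated (NA =
#'   unreplicated).
#' @param params An [smc_params()].
#' @return Speed(s) in kb/min.
#' @export
motor_speed <- function(pos, dir, age_s, params) {
  to_ter <- pos * dir >= 0
  base <- ifelse(to_ter, params$v_to_ter, params$v_to_ori)
  m <- rep_len(memory_factor(age_s, params$t_memory), length(to_ter))
  m[!to_ter] <- 1
  base * m
}

#' Classify a motor-fork encounter within one step
#'
#' An encounter occurs when the motor's path over the step crosses the
#' fork's path (interval crossing, so no tunnelling at any speed). The type
#' is `HEAD_ON` when motor and fork travel in opposite directions and
#' `HEAD_TO_TAIL` when the motor catches the fork from behind.
#'
#' @param motor_from,motor_to Motor position at the start/end of the step
#'   (signed bp).
#' @param motor_dir Motor travel direction (-1/+1).
#' @param fork_from,fork_to Fork position at the start/end of the step.
#' @param fork_dir Fork travel direction (-1 for the left fork, +1 right).
#' @return Character vector: `"none"`, `"HEAD_ON"` or `"HEAD_TO_TAIL"`.
#' @export
detect_encounter <- function(motor_from, motor_to, motor_dir,
                             fork_from, fork_to, fork_dir) {
  d0 <- motor_from - fork_from
  d1 <- motor_to - fork_to
  crossed <- d0 * d1 < 0 | (d0 != 0 & d1 == 0)
  type <- ifelse(!crossed, "none",
                 ifelse(motor_dir == fork_dir, "HEAD_TO_TAIL", "HEAD_ON"))
  type
}

#' Draw the outcome of a blocked motor
#'
#' In the combined model, independent exponential clocks with means
#' `tau_unload` and `tau_bypass` compete; the earlier one fires, giving
#' expected pause `1/(1/tau_unload + 1/tau_bypass)` and unload probability
#' `tau_bypass / (tau_unload + tau_bypass)`. The single-rule models are the
#' limits with one (or both, for blocking-only) clock disabled.
#'
#' @param n Number of independent draws.
#' @param params An [smc_params()] (engagement model and taus).
#' @return A data.frame with columns `outcome` (`"UNLOAD"`, `"BYPASS"` or
#'   `"BLOCK"`) and `wait` (seconds; `Inf` for permanent blocks).
#' @seealso [expected_block_outcome()]
#' @export
resolve_block <- function(n, params) {
  taus <- effective_taus(params)
  U <- if (is.finite(taus[1])) stats::rexp(n, 1 / taus[1]) else rep(Inf, n)
  B <- if (is.finite(taus[2])) stats::rexp(n, 1 / taus[2]) else rep(Inf, n)
  wait <- pmin(U, B)
  outcome <- ifelse(!is.finite(wait), "BLOCK",
                    ifelse(U <= B, "UNLOAD", "BYPASS"))
  data.frame(outcome = outcome, wait = wait)
}

#' Closed-form block-outcome statistics
#'
#' Analytic companion of [resolve_block()]: mean pause duration and outcome
#' probabilities for competing exponential unload/bypass clocks.
#'
#' @param tau_unload,tau_bypass Mean waiting times in seconds (may be `Inf`).
#' @return List with `mean_pause` (s), `p_unload`, `p_bypass`.
#' @export
expected_block_outcome <- function(tau_unload, tau_bypass) {
  ru <- if (is.finite(tau_unload)) 1 / tau_unload else 0
  rb <- if (is.finite(tau_bypass)) 1 / tau_bypass else 0
  rate <- ru + rb
  list(mean_pause = if (rate > 0) 1 / rate else Inf,
       p_unload = if (rate > 0) ru / rate else 0,
       p_bypass = if (rate > 0) rb / rate else 0)
}

#' Draw SMC loading positions
#'
#' Loads occur at a parS site with probability proportional to its loading
#' weight, or anywhere else with probability proportional to
#' `background_weight` per bp (uniform position).
#'
#' @param n Number of loads.
#' @param genome A [genome_spec()].
#' @param params An [smc_params()].
#' @return Signed bp positions.
#' @export
sample_load_positions <- function(n, genome, params) {
  w_sites <- genome$parS_weight * params$parS_weight
  w_bg <- params$background_weight * genome$length
  w <- c(w_sites, w_bg)
  if (sum(w) <= 0) stop("all loading weights are zero")
  pick <- sample.int(length(w), n, replace = TRUE, prob = w)
  pos <- numeric(n)
  at_site <- pick <= length(w_sites)
  pos[at_site] <- genome$parS_bp[pick[at_site]]
  nbg <- sum(!at_site)
  if (nbg) pos[!at_site] <-
      linear_to_signed(stats::runif(nbg, 0, genome$length), genome)
  pos
}
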