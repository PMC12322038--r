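#' Experimental protocol timelines
#'
#' A protocol is a time-ordered list of events, in minutes relative to
#' T = 0 (the onset of replication initiation): temperature shifts
#' (`SET_TEMP`, gating initiation through the temperature-sensitive
#' initiation allele: 30 degC permissive, 42 degC restrictive), inducer
#' addition (`ADD_IPTG`, gating SMC loading after a fixed lag), polymerase
#' inhibitor addition (`ADD_HPURA`, stalling all replication forks in place
#' while retaining the replisome), and `SAMPLE` times at which observables
#' are emitted.
#'
#' @param events A data.frame with columns `time` (minutes), `kind` (one of
#'   `"SET_TEMP"`, `"ADD_IPTG"`, `"ADD_HPURA"`, `"SAMPLE"`) and `value`
#'   (temperature for SET_TEMP events, NA otherwise).
#' @param initial_temp Temperature before the first SET_TEMP event
#'   (default 42, the restrictive temperature).
#' @return An object of class `protocol`.
#' @seealso [protocol_events()], [env_at()]
#' @export
protocol <- function(events, initial_temp = 42) {
  stopifnot(is.data.frame(events),
            all(c("time", "kind") %in% names(events)))
  if (!"value" %in% names(events)) events$value <- NA_real_
  ok_kind <- c("SET_TEMP", "ADD_IPTG", "ADD_HPURA", "SAMPLE")
  if (!all(events$kind %in% ok_kind))
    stop("unknown event kind; must be one of ", paste(ok_kind, collapse = ", "))
  if (is.unsorted(events$time))
    stop("protocol events must be sorted by time")
  if (sum(events$kind == "ADD_IPTG") > 1L)
    stop("at most one ADD_IPTG event is allowed")
  if (sum(events$kind == "ADD_HPURA") > 1L)
    stop("at most one ADD_HPURA event is allowed")
  st <- events$kind == "SET_TEMP"
  if (any(st) && !all(events$value[st] %in% c(30, 42)))
    stop("SET_TEMP value must be 30 or 42")
  structure(list(events = events, initial_temp = initial_temp),
            class = "protocol")
}

#' Build a protocol from event shorthand
#'
#' Convenience constructor for the protocols used in the study: an optional
#' permissive-temperature window `[perm_start, perm_start + perm_dur]`
#' during which replication can initiate, optional IPTG and HPUra addition
#' times, and sampling times.
#'
#' @param perm_start Start of the 30 degC permissive window (minutes), or
#'   `NULL` for a G1-arrest control that never initiates.
#' @param perm_dur Duration of the permissive window (minutes, default 15).
#' @param iptg Time of IPTG addition, or `NULL` (constitutive strains carry
#'   no IPTG event and are run with `constitutive_loading = TRUE`).
#' @param hpura Time of HPUra addition, or `NULL`.
#' @param samples Numeric vector of sampling times (minutes).
#' @return A [protocol()].
#' @export
protocol_events <- function(perm_start = 0, perm_dur = 15, iptg = NULL,
                            hpura = NULL, samples = numeric()) {
  ev <- data.frame(time = numeric(), kind = character(), value = numeric())
  add <- function(time, kind, value = NA_real_)
    rbind(ev, data.frame(time = time, kind = kind, value = value))
  if (!is.null(perm_start)) {
    ev <- add(perm_start, "SET_TEMP", 30)
    ev <- add(perm_start + perm_dur, "SET_TEMP", 42)
  }
  if (!is.null(iptg)) ev <- add(iptg, "ADD_IPTG")
  if (!is.null(hpura)) ev <- add(hpura, "ADD_HPURA")
  for (s in samples) ev <- add(s, "SAMPLE")
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  protocol(ev)
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>\n")
  ev <- x$events
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  t=%6.1f min  %s%s\n", ev$time[i], ev$kind[i],
                ifelse(is.na(ev$value[i]), "", paste0(" -> ", ev$value[i]))))
  invisible(x)
}

#' Instantaneous environment implied by a protocol
#'
#' Deterministic, piecewise-constant in `t` with breakpoints only at event
#' times (plus the SMC loading lag after IPTG). Initiation is allowed only
#' while the temperature is 30 degC (permissive for the ts initiation
#' allele); forks are stalled from the HPUra time onward (monotone); SMC
#' loading is active from `IPTG time + loading_lag`, or always for
#' constitutive strains.
#'
#' @param protocol A [protocol()].
#' @param t Time in minutes.
#' @param constitutive_loading If `TRUE`, SMC loading is always active.
#' @param loading_lag Dead time between IPTG addition and loading onset
#'   (minutes, default 5).
#' @return A list with fields `temperature`, `initiation_allowed`,
#'   `forks_stalled`, `smc_loading_active`.
#' @export
env_at <- function(protocol, t, constitutive_loading = FALSE,
                   loading_lag = 5) {
  stopifnot(inherits(protocol, "protocol"), length(t) == 1L, is.finite(t))
  ev <- protocol$events
  temp <- protocol$initial_temp
  st <- ev[ev$kind == "SET_TEMP" & ev$time <= t, , drop = FALSE]
  if (nrow(st)) temp <- st$value[nrow(st)]
  hp <- ev$time[ev$kind == "ADD_HPURA"]
  ip <- ev$time[ev$kind == "ADD_IPTG"]
  list(temperature = temp,
       initiation_allowed = temp == 30,
       forks_stalled = length(hp) > 0 && t >= hp,
       smc_loading_active = constitutive_loading ||
         (length(ip) > 0 && t >= ip + loading_lag))
}

# event-time accessors -------------------------------------------------------

protocol_time_of <- function(protocol, kind) {
  tt <- protocol$events$time[protocol$events$kind == kind]
  if (length(tt)) tt[1] else NA_real_
}

protocol_samples <- function(protocol) {
  protocol$events$time[protocol$events$kind == "SAMPLE"]
}

# temperature schedule as a step function: data.frame(time, temp), first row
# at -Inf-equivalent start
protocol_temp_schedule <- function(protocol, t_start) {
  ev <- protocol$events
  st <- ev[ev$kind == "SET_TEMP", , drop = FALSE]
  data.frame(time = c(t_start, st$time), temp = c(protocol$initial_temp, st$value))
}

# time at which SMC loading becomes active (0-width for constitutive)
loading_start_time <- function(protocol, constitutive_loading, loading_lag = 5) {
  if (constitutive_loading) return(-Inf)
  ip <- protocol_time_of(protocol, "ADD_IPTG")
  if (is.na(ip)) Inf else ip + loading_lag
}
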