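---
title: "Modelling SMC-replisome collisions on a circular chromosome"
author: "smcollide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SMC-replisome collisions on a circular chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcollide)
set.seed(1)
```

## The system being modelled

Bacterial SMC (condensin) complexes load at parS sites, usually near the
replication origin, and extrude DNA loops with two motors translocating in
opposite directions, juxtaposing ("zipping") the two chromosome arms. The
replisome starts at the same origin and moves toward the terminus. Because
both machines run on the same track at comparable speeds (~71.5 kb/min per
SMC motor versus ~66 kb/min per fork at 42 degrees C), encounters are
unavoidable: a motor meeting a fork face-on is a *head-on* collision, a
motor catching a fork from behind is *head-to-tail*.

`smcollide` simulates a cell population carrying one circular chromosome
through the experimental designs used to study these collisions in
*B. subtilis*: a temperature-sensitive initiation allele synchronizes one
round of replication (30 degrees C permissive, 42 degrees C restrictive),
IPTG-inducible ParB gates SMC loading with a ~5 min lag, and the PolC
inhibitor HPUra freezes forks in place while leaving the replisome on the
DNA. Forward models convert simulated ensembles into the three measurement
types of such experiments -- marker frequency analysis (MFA) profiles,
ChIP-like occupancy tracks, and Hi-C contact maps -- and estimators invert
them back to kinetic parameters.

Coordinates are signed base pairs centred on the origin; degrees map
linearly (`bp = deg/360 * length`, default length 4,033,000 bp), so the
terminus is at +/-180 degrees.

## Replisome model

Five parameters describe synchronized replication
(see `replisome_params()`):

* `f_pre = 0.18` -- fraction of cells that escaped the G1 arrest and carry
  a fork pair at T = 0, with uniform arm progress. This produces the
  shallow origin-to-terminus tilt of the T = 0 MFA.
* `t_init_mean = 5` min -- mean of the exponential replisome-loading delay
  while the temperature is permissive. With the standard 15-min window
  this gives an initiation fraction of `1 - exp(-15/5) ~ 0.95` and the
  sloped (rather than vertical) replicated/unreplicated boundary.
* `v30 = 40`, `v42 = 66` kb/min -- elongation speeds at the two
  temperatures. Only `v42` is directly constrained by the data this
  package emulates; `v30` is a typical value for the lower temperature and
  only shifts the boundary intercept, not its slope.
* `p_stall = 0.004` per fork per minute -- irreversible spontaneous
  stalling, producing the late shallow slope of post-completion profiles.

`simulate_replication()` steps a population with `step_forks()` (cells
initiating within a step start at a uniform time inside it, which keeps
fork positions off the step lattice); the joint simulator instead uses the
exact piecewise-linear trajectory implied by the speed schedule, because
the fork-memory factor needs the exact time at which every locus was
replicated.

## SMC model

Each cell carries a pool of `n_smc = 40` complexes. Bound complexes occupy
a loading position (drawn with strong parS preference; the default
background weight puts >90% of loads at parS) and two motor positions; the
motors translocate away from the loading site at `v_to_ter = 71.5` and
`v_to_ori = 49` kb/min, stop at the terminus, and the whole complex
dissociates spontaneously with mean residence `tau_dissoc = 1200` s.
Unbound complexes reload at `load_rate = 1/60` per second, which keeps
~95% of the pool bound at steady state and makes the control zipping
extent 15 min after induction (~700-730 kb per arm) match observation.

**Collisions.** Encounters are detected by interval crossing (motor and
fork paths within one step), so nothing tunnels at any speed. A collided
motor is first blocked at the fork -- carried with it if the fork still
moves, which for a head-on collision means being pushed backward -- and
then two exponential clocks compete (`resolve_block()`):
unloading of the whole complex (mean `tau_unload = 30` s) versus bypassing
(mean `tau_bypass = 120` s), after which the motor resumes one
`bypass_offset` past the fork. These defaults give a mean pause of
`1/(1/30 + 1/120) = 24` s, 80% unloading and 20% bypassing. The
single-rule models are limits of the same machinery: `block_only`
disables both clocks, `unload_only`/`bypass_only` keep one.

**Fork memory.** Motors traversing recently replicated DNA are slowed:
speed is scaled by `clip(age/t_memory, 0, 1)` where `age` is the time
since the motor's current locus was replicated and `t_memory = 700` s.
For a fork moving at constant speed this is identical to a linear ramp
over the `t_memory * v_fork ~ 770` kb behind the fork, and it resolves on
its own at stalled forks -- a fork older than `t_memory` imposes no
slowdown, which is why stalled-fork experiments show no trailing arc. The
slowdown applies only to terminus-directed motors (those translocating in
the fork's direction, into ever-younger DNA). An origin-directed motor
moves away from the fork onto older DNA; treating it as unhindered is what
produces the observed upward tilt of the trailing arc -- if both motors
were slowed, an SMC loaded just behind the fork would crawl symmetrically
and the arc would start perpendicular instead.

A consequence worth spelling out: a chasing motor's instantaneous speed is
`v_to_ter * z / (t_memory * v_fork)` at distance `z` behind the fork, so
the stable trailing distance is `z* = v_fork/v_to_ter * t_memory * v_fork`
(~711 kb at defaults), approached with time constant
`t_memory * v_fork / v_to_ter` (~11 min). Motors loaded shortly after fork
passage therefore chase at ~10 kb/min for several minutes -- about 0.2x
the origin-directed speed -- while motors loaded long after passage run at
full speed until they reach the memory zone edge, ~770 kb behind the fork.
Both regimes are visible in `simulate_arc2()` output.

`simulate_arc2()` is the deliberately reduced model used for the
trailing-arc analysis: independent motor pairs against a single
constant-speed fork, no blocking, pushing, unloading or SMC-SMC
interactions, so that the memory effect is isolated.

## Observables

* `compute_mfa()` -- per-bin mean copy number (1 or 2 per cell per locus;
  population values in [1, 2]), 10-kb bins by default.
* `compute_occupancy()` -- Gaussian-footprint density (5-kb sd) of bound
  motor positions plus loading sites, reads-per-million normalized, 1-kb
  bins by default with experiment-like comparisons at 10 kb.
* `profile_ratio()` -- log2 ratio of two tracks in 5-kb bins with a
  documented pseudocount, the convention for following SMC translocation
  between time points.
* `compute_contact_map()` -- a unit-mass mixture of a Gaussian-smeared
  anchor-pair layer and a `(s0 + d)^-1` distance-decay background on
  circular distance (`s0 = 30` kb, mixture weight 0.5, smear 20 kb, 10-kb
  bins). The published map-generation recipe is not printed, so these are
  exposed configuration values; none of the package's estimators depend on
  their exact values because extraction happens on the observed/expected
  (distance-normalized) map.
* `zipping_extent()` -- per-arm reach of the secondary diagonal: a band
  scan outward from the loading bin (covering tilts up to 6:1) thresholded
  at 20% of the proximal ridge median, with a 100-kb gap tolerance so that
  loading-history gaps in the arc do not truncate the measurement while
  isolated background contacts do not extend it. Motors park at the
  terminus, so extents are capped there and timepoints for slope
  estimation should stay inside the linear regime.
* `arc_speed_ratio()` -- through-origin regression of the
  decreasing-coordinate motor displacement on the increasing-coordinate
  one; 1 means a perpendicular secondary diagonal, values below 1 an
  upward tilt (slower terminus-directed motor).

## Estimators

* `estimate_fork_speed()` regresses the midpoint crossing of the MFA
  boundary on time, per arm. With pre-existing forks the distal baseline
  rises over time and biases the naive version low; passing the T = 0
  profile pins the unreplicated plateau at the time-invariant `1 + f_pre`
  (the pre-existing coverage is saturated everywhere behind its own
  front). Spontaneous stalling still bleeds about 1 kb/min from the slope
  at the default `p_stall`; this is within the reported tolerances and is
  a property of the estimator, not of the fork speed.
* `estimate_pre_existing_fraction()` inverts the origin/terminus window
  ratio exactly for the finite window geometry
  (`f = (r - 1) / ((1 - chi_o) - r (1 - chi_t))`); the naive `ratio - 1`
  is ~2 points low at the default +/-5% windows.
* `estimate_initiation_fraction()` uses the origin peak height over the
  known copy-number scale, subtracting the pre-existing contribution
  (estimated from the T = 0 profile) -- see the function documentation for
  the exact formula and the slope-based scale recovery used for
  read-sampled (relative) tracks.
* `estimate_motor_speed()` and `estimate_bypass_delay()` are the extent
  slope and deficit arithmetic; delays are reported raw and rounded to the
  nearest minute, mirroring how such numbers are quoted.
* `gof_score()` is the sum of squared residuals of unit-sum-normalized
  profiles, masking +/-20 kb around parS and zero-coverage bins: scale
  free, deterministic, and sufficient to rank engagement models.
* `sweep_collision_params()` scores a (tau_unload, tau_bypass) grid
  against a reference occupancy and annotates the
  `tau_bypass >= 2 tau_unload` region; near-optimal plateaus rather than a
  unique optimum are expected, as in the underlying analysis.
* `sweep_fork_memory()` scores memory duration against reference trailing
  arc points on two features: the terminus-directed displacement profiled
  against the origin-directed displacement (an age proxy), and the mean
  motor-to-fork trailing gap. The gap term matters: the displacement curve
  alone is nearly degenerate between memory duration and effective time,
  while the trailing gap scales directly with the memory extent. The
  uncertainty band is derived from the quadratic curvature of the score
  profile (the half-width at twice the minimum score), and with
  arc ensembles of ~1000 pairs the recovered duration is reliable to
  about +/-100 s -- the same order as the uncertainty quoted for this
  quantity from experimental arcs.

## Synthetic data and scenarios

`scenario()` bundles the experimental designs (genome with one engineered
parS site, protocol, parameters, sample times): induced loading with
free-running forks (`FIG1C`, `FIG7A`), constitutive loading (`FIG2`,
`FIG7B`), a G1-arrest control (`FIG5A`), two-sided head-to-tail collisions
with stalled forks at an ori-proximal site (`FIG4`), and one-sided
head-to-tail or head-on collisions with forks stalled after ~1169 kb of
leftward progression (`FIG5B`, `FIG5C`; the stall time is computed from
the configured speeds rather than hard-coded). `generate_dataset()` writes
read-sampled bedGraph tracks and count-sampled contact matrices per sample
time plus a JSON manifest carrying every ground-truth parameter and seed.
Counting noise is multinomial (no overdispersion): comparisons happen at
5-10-kb bins where count noise is small.

What the generator does *not* emulate: sequencing bias (GC, mappability),
restriction-fragment granularity in contact maps, replication restart or
DNA degradation, explicit transcription (absorbed into the
direction-dependent motor speeds), XerD-mediated unloading at the terminus
(converging motors simply park there -- occupancy near the terminus is
therefore inflated relative to real data and feature extractors exclude
it), and 3D polymer physics beyond the distance-decay background. Tests
passing on these synthetic data show the estimators invert this model
class; they do not certify performance on real sequencing artefacts.

## Numerical choices

The SMC engine advances in 1-s steps (motor displacement ~1.2 kb, well
below bin size); encounter detection is by interval crossing, so the step
size affects only the discretization of collision times. Fork trajectories
and locus replication ages are closed-form. Blocked-motor clocks are drawn
once at block entry (memoryless, so equivalent to per-step hazards), and
clocks are discarded if the blocking fork finishes replication, releasing
the motor unblocked. Contact-map balancing is plain Sinkhorn iteration,
preserving symmetry and total mass. All stochastic entry points take
explicit seeds; ensembles are vectorized across all complexes of all
cells, so populations of a few hundred cells simulate in seconds.

Default problem sizes used by the test-suite and the acceptance script --
500-5000 cells for MFA estimators, 300 cells for contact-map time courses,
~1000 motor pairs for arc sweeps -- were chosen as the smallest ensembles
at which each estimator's sampling error is comfortably inside the
tolerance it is tested against.

## Interface

The package is used from R; the exported functions, the scenario configs
(YAML, versioned schema; see
`system.file("extdata", "scenario_FIG5B.yaml", package = "smcollide")`)
and `scripts/acceptance.R` are the interface. 1-D tracks are exchanged as
bedGraph, matrices as dense TSV or sparse upper-triangle triplets, all
with header metadata, on 0-based half-open linear coordinates with the
origin at position 0.

## Known limitations

* The terminus is absorbing for motors (no XerD unloading), so long
  simulations accumulate occupancy there.
* Whether head-on pushback stores slack or shrinks the loop is not
  resolved by the data; here positions simply move with the fork.
* SMC-SMC interactions are ignored (motors pass freely), consistent with
  reported bypass of other SMC complexes, and the reduced trailing-arc
  model omits replisome blocking by construction.
* The initiation-fraction estimator assumes the mid-replication sample is
  taken while initiated forks have covered the origin window but not the
  fit window; the defaults match the standard synchronized protocol and
  need adjusting for other designs.
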