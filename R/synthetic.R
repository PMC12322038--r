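#' Named experimental scenarios
#'
#' Pre-configured scenario fixtures mirroring the study designs this
#' package models. Each scenario bundles a genome (single engineered parS
#' site), a protocol (temperature-gated initiation window, IPTG-gated or
#' constitutive SMC loading, optional HPUra fork stalling), parameter sets
#' and sample times:
#'
#' * `FIG1C`: parS -59 deg, IPTG at T = 0, free-running forks (replication
#'   time course).
#' * `FIG2`: parS -27 deg, constitutive loading, free-running forks.
#' * `FIG4`: parS -1 deg, HPUra + IPTG at 15 min (two-sided head-to-tail
#'   collision with stalled forks; symmetric motor speeds).
#' * `FIG5A`: G1-arrest control, parS -59 deg, IPTG, no replication.
#' * `FIG5B`: parS -59 deg; forks run until the leftward fork is ~1169 kb
#'   from ori, then HPUra + IPTG (one-sided head-to-tail, stalled).
#' * `FIG5C`: as FIG5B but parS -117 deg (head-on collision, stalled).
#' * `FIG7A`: parS -59 deg, IPTG at T = 0, free-running forks (head-on with
#'   moving forks, then trailing).
#' * `FIG7B`: parS -59 deg, constitutive loading, free-running forks.
#'
#' The HPUra time in FIG5B/FIG5C is computed from the replisome speeds so
#' the stall position tracks the configured kinetics.
#'
#' @param name Scenario name (see above).
#' @param genome_length Chromosome length in bp.
#' @return A list with fields `name`, `genome`, `protocol`, `rep_params`,
#'   `smc_params`, `sample_times`, `constitutive_loading`.
#' @export
scenario <- function(name = c("FIG1C", "FIG2", "FIG4", "FIG5A", "FIG5B",
                              "FIG5C", "FIG7A", "FIG7B"),
                     genome_length = 4033000) {
  name <- match.arg(name)
  rp <- replisome_params()
  sp <- smc_params()
  # time at which the leftward fork has progressed ~1169 kb from ori
  t_star <- 15 + (1169 - 15 * rp$v30) / rp$v42
  cfg <- switch(name,
    FIG1C = list(parS = -59, perm = 0, iptg = 0, hpura = NULL,
                 samples = c(0, 10, 20, 30, 45, 60), constitutive = FALSE),
    FIG2 = list(parS = -27, perm = 0, iptg = NULL, hpura = NULL,
                samples = seq(0, 30, by = 5), constitutive = TRUE),
    FIG4 = list(parS = -1, perm = 0, iptg = 15, hpura = 15,
                samples = 15 + c(15, 20, 25, 30), constitutive = FALSE),
    FIG5A = list(parS = -59, perm = NULL, iptg = 0, hpura = NULL,
                 samples = c(15, 20, 25, 30), constitutive = FALSE),
    FIG5B = list(parS = -59, perm = 0, iptg = t_star, hpura = t_star,
                 samples = t_star + c(15, 25), constitutive = FALSE),
    FIG5C = list(parS = -117, perm = 0, iptg = t_star, hpura = t_star,
                 samples = t_star + c(15, 25), constitutive = FALSE),
    FIG7A = list(parS = -59, perm = 0, iptg = 0, hpura = NULL,
                 samples = c(15, 20, 25, 30, 40), constitutive = FALSE),
    FIG7B = list(parS = -59, perm = 0, iptg = NULL, hpura = NULL,
                 samples = c(10, 15, 20, 25, 30, 40), constitutive = TRUE))
  if (name == "FIG4") { # origin-proximal parS: symmetric motor speeds
    sp$v_to_ori <- sp$v_to_ter
  }
  g <- genome_spec(length = genome_length, parS_deg = cfg$parS)
  pr <- protocol_events(perm_start = cfg$perm, perm_dur = 15,
                        iptg = cfg$iptg, hpura = cfg$hpura,
                        samples = cfg$samples)
  list(name = name, genome = g, protocol = pr, rep_params = rp,
       smc_params = sp, sample_times = cfg$samples,
       constitutive_loading = cfg$constitutive)
}

#' Read-sample a profile
#'
#' Multinomial read counts with per-bin probabilities proportional to the
#' profile values (emulating finite sequencing depth).
#'
#' @param profile A `profile1d`.
#' @param depth Total read count (>= 0).
#' @param seed Integer RNG seed (optional).
#' @return A `profile1d` of kind COUNTS.
#' @export
sample_profile_reads <- function(profile, depth, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nb <- length(profile$values)
  counts <- if (depth == 0) numeric(nb) else
    as.numeric(stats::rmultinom(1, depth, prob = profile$values))
  profile1d(counts, profile$genome, profile$bin_size, kind = "COUNTS",
            normalization = sprintf("reads, depth %g", depth))
}

#' Count-sample a contact map
#'
#' Multinomial counts on the upper triangle (including the diagonal),
#' mirrored so the output is exactly symmetric.
#'
#' @param map A `contact_map`.
#' @param depth Total pair count (>= 0).
#' @param seed Integer RNG seed (optional).
#' @return A `contact_map` of counts.
#' @export
sample_hic_counts <- function(map, depth, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(map$matrix)
  ut <- upper.tri(map$matrix, diag = TRUE)
  p <- map$matrix[ut]
  counts <- matrix(0, nb, nb)
  if (depth > 0) {
    draw <- as.numeric(stats::rmultinom(1, depth, prob = p))
    counts[ut] <- draw
    counts <- counts + t(counts) - diag(diag(counts))
  }
  contact_map(counts, map$genome, map$bin_size, normalization = "counts")
}

#' Generate a synthetic dataset bundle with known ground truth
#'
#' Runs the joint simulation for a scenario and writes, per sample time,
#' read-sampled MFA and occupancy bedGraph tracks and a count-sampled
#' contact-map matrix, plus a manifest recording every ground-truth
#' parameter and the seed, so each file is round-trippable by the
#' inference module.
#'
#' @param scen A [scenario()] list.
#' @param outdir Output directory (created if needed).
#' @param n_cells Cells to simulate (default 200).
#' @param depth_mfa,depth_chip,depth_hic Sampling depths (reads / reads /
#'   pair counts) per sample time.
#' @param seed Integer seed.
#' @param mfa_bin,chip_bin,hic_bin Bin sizes in bp.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
generate_dataset <- function(scen, outdir, n_cells = 200, depth_mfa = 2e5,
                             depth_chip = 2e5, depth_hic = 5e5, seed = 1,
                             mfa_bin = 10000, chip_bin = 1000,
                             hic_bin = 10000) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  sim <- simulate_joint(scen$protocol, scen$rep_params, scen$smc_params,
                        scen$genome, n_cells,
                        constitutive_loading = scen$constitutive_loading)
  files <- character()
  for (sn in sim$snapshots) {
    tag <- sprintf("t%03d", round(sn$time))
    mfa <- sample_profile_reads(
      compute_mfa(sn$forks, scen$genome, mfa_bin), depth_mfa)
    f1 <- file.path(outdir, paste0("mfa_", tag, ".bedgraph"))
    write_bedgraph(mfa, f1)
    occ <- compute_occupancy(sn$smcs, scen$genome, chip_bin)
    occ_counts <- if (sum(occ$values) > 0)
      sample_profile_reads(occ, depth_chip) else
      profile1d(numeric(length(occ$values)), scen$genome, chip_bin,
                kind = "COUNTS", normalization = "reads, depth 0")
    f2 <- file.path(outdir, paste0("chip_", tag, ".bedgraph"))
    write_bedgraph(occ_counts, f2)
    hic <- sample_hic_counts(
      compute_contact_map(sn$smcs, scen$genome, hic_bin), depth_hic)
    f3 <- file.path(outdir, paste0("hic_", tag, ".matrix.tsv"))
    write_contact_matrix(hic, f3)
    files <- c(files, f1, f2, f3)
  }
  manifest <- list(
    schema_version = 1,
    scenario = scen$name,
    seed = seed,
    n_cells = n_cells,
    depths = list(mfa = depth_mfa, chip = depth_chip, hic = depth_hic),
    genome = list(length = scen$genome$length,
                  parS_deg = scen$genome$parS_deg,
                  parS_weight = scen$genome$parS_weight),
    truth = list(rep_params = unclass(scen$rep_params),
                 smc_params = unclass(scen$smc_params)),
    sample_times = scen$sample_times,
    constitutive_loading = scen$constitutive_loading,
    files = basename(files),
    package_version = as.character(utils::packageVersion("smcollide")),
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
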