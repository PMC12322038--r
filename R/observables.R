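#' Binned 1-D genomic track
#'
#' Bins are laid out on linear `[0, length)` coordinates (origin at 0, left
#' arm in the upper half) with the last bin possibly short; values are
#' non-negative reals.
#'
#' @param values Per-bin values.
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp.
#' @param kind One of `"MFA"`, `"OCCUPANCY"`, `"RATIO"`, `"COUNTS"`.
#' @param normalization Free-text normalization tag.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(values, genome, bin_size,
                      kind = c("MFA", "OCCUPANCY", "RATIO", "COUNTS"),
                      normalization = "none") {
  kind <- match.arg(kind)
  nb <- n_bins(genome, bin_size)
  if (length(values) != nb)
    stop(sprintf("expected %d bins, got %d values", nb, length(values)))
  structure(list(values = as.numeric(values), bin_size = bin_size,
                 genome = genome, kind = kind,
                 normalization = normalization),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %s, %d bins of %g bp (%s)\n", x$kind,
              length(x$values), x$bin_size, x$normalization))
  invisible(x)
}

#' Binned symmetric contact map
#'
#' @param matrix Symmetric non-negative matrix (bins as in [profile1d()]).
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @param normalization `"raw"`, `"model"` or `"balanced"`.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(matrix, genome, bin_size = 10000,
                        normalization = "raw") {
  nb <- n_bins(genome, bin_size)
  stopifnot(is.matrix(matrix), nrow(matrix) == nb, ncol(matrix) == nb)
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(abs(matrix), 1))
    stop("contact map must be symmetric")
  structure(list(matrix = matrix, genome = genome, bin_size = bin_size,
                 normalization = normalization),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d bins of %g bp (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size, x$normalization))
  invisible(x)
}

# circular Gaussian smoothing of a per-bin vector (sd in bins)
smooth_circular <- function(values, sd_bins) {
  if (sd_bins <= 0) return(values)
  nb <- length(values)
  hw <- min(ceiling(4 * sd_bins), floor((nb - 1) / 2))
  kern <- stats::dnorm(seq(-hw, hw), sd = sd_bins)
  kern <- kern / sum(kern)
  idx <- outer(seq_len(nb), seq(-hw, hw), function(i, o) ((i + o - 1) %% nb) + 1L)
  as.numeric(matrix(values[idx], nrow = nb) %*% kern)
}

#' Marker frequency analysis (MFA) profile from fork snapshots
#'
#' Per-bin mean copy number over cells: copy 2 inside the replicated
#' interval `[left_pos, right_pos]` (through the origin), copy 1 outside.
#'
#' @param forks Fork snapshot data.frame (one sample time), schema of
#'   [init_population()].
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @param normalize If TRUE, divide by the unreplicated baseline (all-1
#'   population), i.e. report relative marker frequency.
#' @return A `profile1d` of kind MFA; values in \[1, 2\] (before read
#'   sampling).
#' @export
compute_mfa <- function(forks, genome, bin_size = 10000, normalize = FALSE) {
  if (!nrow(forks)) stop("empty ensemble")
  x <- bin_centers_signed(genome, bin_size)
  init <- forks$initiated
  lp <- forks$left_pos[init]; rp <- forks$right_pos[init]
  n <- nrow(forks)
  vals <- vapply(x, function(xi) {
    cov <- if (xi < 0) sum(lp <= xi) else sum(rp >= xi)
    1 + cov / n
  }, numeric(1))
  if (normalize) vals <- vals / 1
  profile1d(vals, genome, bin_size, kind = "MFA",
            normalization = if (normalize) "baseline" else "copy_number")
}

#' SMC occupancy profile from ensemble anchor positions
#'
#' Kernel-smoothed density of all bound motor positions plus loading sites,
#' normalized reads-per-million style (values sum to 1e6).
#'
#' @param smcs Anchor-pair data.frame from a [simulate_joint()] snapshot
#'   (columns `pos1`, `pos2`, `load_pos`).
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 1 kb; experiment-like comparisons
#'   are at 10 kb).
#' @param footprint_sd Gaussian footprint width in bp (default 5 kb).
#' @param include_load_sites Include loading positions (default TRUE).
#' @return A `profile1d` of kind OCCUPANCY (RPM-normalized; all-zero when no
#'   complex is bound).
#' @export
compute_occupancy <- function(smcs, genome, bin_size = 1000,
                              footprint_sd = 5000,
                              include_load_sites = TRUE) {
  nb <- n_bins(genome, bin_size)
  pos <- c(smcs$pos1, smcs$pos2, if (include_load_sites) smcs$load_pos)
  if (!length(pos))
    return(profile1d(numeric(nb), genome, bin_size, kind = "OCCUPANCY",
                     normalization = "rpm"))
  counts <- tabulate(bin_of(pos, genome, bin_size), nbins = nb)
  sm <- smooth_circular(counts, footprint_sd / bin_size)
  profile1d(sm * 1e6 / sum(sm), genome, bin_size, kind = "OCCUPANCY",
            normalization = "rpm")
}

# average adjacent bins to a coarser bin size (integer multiple)
rebin_profile <- function(p, out_bin) {
  if (out_bin == p$bin_size) return(p)
  k <- out_bin / p$bin_size
  if (k != round(k)) stop("out_bin must be a multiple of the input bin size")
  nb_out <- n_bins(p$genome, out_bin)
  grp <- ceiling(seq_along(p$values) / k)
  vals <- as.numeric(tapply(p$values, grp, mean))
  if (length(vals) != nb_out) vals <- vals[seq_len(nb_out)]
  profile1d(vals, p$genome, out_bin, kind = p$kind,
            normalization = p$normalization)
}

#' Log2 ratio of two profiles
#'
#' `log2((a + pseudocount) / (b + pseudocount))`, rebinned to `out_bin`
#' (default 5 kb), the convention used for ratio tracks that follow SMC
#' translocation between time points.
#'
#' @param a,b `profile1d` objects on the same genome and binning.
#' @param out_bin Output bin size in bp.
#' @param pseudocount Added to both profiles before the ratio (default 1 on
#'   the RPM scale).
#' @return A `profile1d` of kind RATIO (log2 scale).
#' @export
profile_ratio <- function(a, b, out_bin = 5000, pseudocount = 1) {
  if (!identical(a$bin_size, b$bin_size) ||
      length(a$values) != length(b$values) ||
      a$genome$length != b$genome$length)
    stop("profiles must share genome and binning")
  ra <- rebin_profile(a, out_bin)
  rb <- rebin_profile(b, out_bin)
  if (any(rb$values + pseudocount <= 0)) stop("denominator not positive")
  vals <- log2((ra$values + pseudocount) / (rb$values + pseudocount))
  p <- profile1d(pmax(vals, -Inf), a$genome, out_bin, kind = "RATIO",
                 normalization = sprintf("log2, pseudocount %g", pseudocount))
  p
}

#' Simulated Hi-C contact map from SMC anchor pairs
#'
#' The map is a mixture of an SMC loop layer (Gaussian-smeared density of
#' the bound `(pos1, pos2)` anchor pairs, symmetrized) and a distance-decay
#' polymer background `(s0 + d)^-background_exponent` on circular distance
#' `d`; both layers are unit-sum so `loop_weight` sets their mixture.
#'
#' @param smcs Anchor-pair data.frame (columns `pos1`, `pos2`); may have
#'   zero rows (pure background).
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @param background_exponent Distance-decay exponent (default 1).
#' @param s0 Distance offset in bp (default 30 kb).
#' @param loop_weight Mixture weight of the loop layer (default 0.5; ignored
#'   when there are no anchor pairs).
#' @param kernel_sd Gaussian smear of anchor positions, bp (default 20 kb).
#' @param balance If TRUE, apply iterative proportional balancing.
#' @return A `contact_map` (unit total mass).
#' @export
compute_contact_map <- function(smcs, genome, bin_size = 10000,
                                background_exponent = 1, s0 = 30000,
                                loop_weight = 0.5, kernel_sd = 20000,
                                balance = FALSE) {
  nb <- n_bins(genome, bin_size)
  ctr <- bin_centers_signed(genome, bin_size)
  # background: power-law decay in circular distance between bin centres
  dmat <- outer(seq_len(nb), seq_len(nb), function(i, j) {
    d <- abs(i - j)
    pmin(d, nb - d) * bin_size
  })
  bg <- (s0 + dmat)^(-background_exponent)
  bg <- bg / sum(bg)
  if (nrow(smcs)) {
    i <- bin_of(smcs$pos1, genome, bin_size)
    j <- bin_of(smcs$pos2, genome, bin_size)
    loops <- matrix(0, nb, nb)
    for (k in seq_along(i)) {
      loops[i[k], j[k]] <- loops[i[k], j[k]] + 1
      loops[j[k], i[k]] <- loops[j[k], i[k]] + 1
    }
    sdb <- kernel_sd / bin_size
    if (sdb > 0) {
      loops <- apply(loops, 2, smooth_circular, sd_bins = sdb)
      loops <- t(apply(loops, 1, smooth_circular, sd_bins = sdb))
      loops <- (loops + t(loops)) / 2
    }
    loops <- loops / sum(loops)
    m <- loop_weight * loops + (1 - loop_weight) * bg
  } else {
    m <- bg
  }
  cm <- contact_map(m, genome, bin_size, normalization = "model")
  if (balance) cm <- balance_contact_map(cm) else cm
}

#' Iterative proportional (matrix balancing) normalization
#'
#' Sinkhorn-style balancing: rows and columns are scaled toward equal sums;
#' symmetry and total mass are preserved.
#'
#' @param map A [contact_map()].
#' @param n_iter Number of iterations (default 50).
#' @return A balanced `contact_map`.
#' @export
balance_contact_map <- function(map, n_iter = 50) {
  m <- map$matrix
  total <- sum(m)
  for (it in seq_len(n_iter)) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    s <- sqrt(rs / mean(rs))
    m <- m / outer(s, s)
  }
  m <- m * total / sum(m)
  contact_map(m, map$genome, map$bin_size, normalization = "balanced")
}

# observed/expected: divide out the mean contact at each circular distance
oe_map <- function(map) {
  nb <- nrow(map$matrix)
  d <- outer(seq_len(nb), seq_len(nb), function(i, j) {
    k <- abs(i - j); pmin(k, nb - k)
  })
  exp_d <- vapply(0:max(d), function(k) mean(map$matrix[d == k]), numeric(1))
  exp_d[exp_d == 0] <- min(exp_d[exp_d > 0])
  map$matrix / exp_d[d + 1L]
}

#' Extent of inter-arm DNA zipping from a contact map
#'
#' Scans the secondary diagonal (inter-arm juxtaposition) outward from the
#' loading site on the observed/expected map. For each displacement `u`
#' down one arm the ridge intensity is the maximum O/E value over anchor
#' partners on the other arm within a tilt band (tilts between about 1:6
#' and 6:1 are covered, so trailing arcs are handled); the arm extent is
#' the largest displacement whose ridge intensity is at least
#' `intensity_threshold_frac` times the median intensity of the proximal
#' ridge segment. Scanning the whole arm (rather than stopping at the
#' first sub-threshold point) makes the tip measurement robust to loading
#' gaps in the arc. Motors stop at the terminus, so each scan is capped
#' there.
#'
#' @param map A [contact_map()].
#' @param load_pos Loading-site position, signed bp.
#' @param intensity_threshold_frac Threshold as a fraction of the proximal
#'   ridge median (default 0.2).
#' @param proximal_bins Number of initial displacements defining the
#'   proximal segment (default 10).
#' @param max_tilt Largest arm-speed asymmetry covered by the search band
#'   (default 6).
#' @param band_slack Extra band half-width in bins (default 5).
#' @param gap_tol Largest below-threshold gap (bp) the arc may contain
#'   before it is considered ended (default 100 kb); keeps isolated
#'   background-load contacts from faking a longer arc while tolerating
#'   loading-history gaps in the real one.
#' @param ter_margin Bins adjacent to the terminus excluded from the
#'   partner search (default 3): converging motors park there, so those
#'   rows carry pile-up contacts rather than arc signal.
#' @return A list with `ccw` and `cw` extents in bp (the decreasing- and
#'   increasing-coordinate arms) and `detected` (FALSE for a flagged null
#'   result when no secondary diagonal is found). The per-displacement
#'   ridge intensities are attached as attribute `ridge`.
#' @export
zipping_extent <- function(map, load_pos, intensity_threshold_frac = 0.2,
                           proximal_bins = 10, max_tilt = 6,
                           band_slack = 5, gap_tol = 1e5, ter_margin = 3) {
  oe <- oe_map(map)
  nb <- nrow(oe)
  bs <- map$bin_size
  start <- bin_of(load_pos, map$genome, map$bin_size)
  wrap <- function(i) ((i - 1L) %% nb) + 1L
  half <- map$genome$length / 2
  # displacement caps: motors stop at the terminus
  cap_ccw <- floor((load_pos + half) / bs) # toward decreasing coordinates
  cap_cw <- floor((half - load_pos) / bs)
  scan_arm <- function(cap_u, cap_w, ccw_first) {
    vapply(seq_len(cap_u), function(u) {
      wmax <- min(cap_w - ter_margin, ceiling(max_tilt * u) + band_slack)
      ws <- 0:max(wmax, 0)
      if (ccw_first)
        max(oe[wrap(start - u), wrap(start + ws)])
      else
        max(oe[wrap(start - ws), wrap(start + u)])
    }, numeric(1))
  }
  ridge_ccw <- scan_arm(cap_ccw, cap_cw, TRUE)
  ridge_cw <- scan_arm(cap_cw, cap_ccw, FALSE)
  gap_bins <- ceiling(gap_tol / bs)
  extent_of <- function(ridge) {
    prox <- stats::median(ridge[seq_len(min(proximal_bins, length(ridge)))])
    if (!is.finite(prox) || prox <= 1.05) return(NA_real_)
    ok <- which(ridge >= intensity_threshold_frac * prox)
    if (!length(ok)) return(NA_real_)
    # extend from the loading site, tolerating gaps up to gap_bins
    last <- 0L
    for (idx in ok) {
      if (idx - last > gap_bins + 1L) break
      last <- idx
    }
    if (last == 0L) return(NA_real_)
    last * bs
  }
  res <- list(ccw = extent_of(ridge_ccw), cw = extent_of(ridge_cw))
  res$detected <- !anyNA(c(res$ccw, res$cw))
  attr(res, "ridge") <- list(ccw = ridge_ccw, cw = ridge_cw)
  res
}

#' Arm-speed ratio from anchor pairs
#'
#' Fits the displacement of the decreasing-coordinate motor against that of
#' the increasing-coordinate motor (both measured from the loading site) by
#' least squares through the origin. A ratio of 1 means a secondary
#' diagonal perpendicular to the main diagonal; for a loading site on the
#' left arm the ratio is terminus-directed over origin-directed speed, so a
#' trailing (slowed) chase gives a ratio well below 1.
#'
#' @param pairs Data.frame with columns `pos1` (decreasing-coordinate
#'   motor) and `pos2`, or a two-column matrix.
#' @param load_pos Loading-site position, signed bp.
#' @return Dimensionless speed ratio (slope of pos1-displacement on
#'   pos2-displacement).
#' @export
arc_speed_ratio <- function(pairs, load_pos) {
  if (is.matrix(pairs)) pairs <- data.frame(pos1 = pairs[, 1], pos2 = pairs[, 2])
  if (nrow(pairs) < 3) stop("need at least 3 arc points")
  d1 <- abs(pairs$pos1 - load_pos)
  d2 <- abs(pairs$pos2 - load_pos)
  if (all(d1 == 0) && all(d2 == 0)) stop("degenerate arc: all points at the loading site")
  if (sum(d2^2) == 0) stop("degenerate arc: no displacement on the reference arm")
  sum(d1 * d2) / sum(d2^2)
}
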