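#' Circular chromosome geometry
#'
#' A `genome_spec` describes the circular bacterial chromosome on which all
#' simulations run. Coordinates are signed base pairs centred on the
#' replication origin (oriC): 0 = ori, positive = right arm (positive
#' degrees), negative = left arm, and +/- `length/2` are the same locus, the
#' replication terminus. Degrees map linearly to base pairs
#' (`bp = deg / 360 * length`).
#'
#' @param length Chromosome length in bp. Default 4,033,000 (PY79 scale).
#' @param parS_deg Numeric vector of parS site positions in degrees, each in
#'   (-180, 180].
#' @param parS_weight Loading weight (dimensionless, >= 0) per parS site,
#'   recycled. Weights are relative propensities per *site*; background
#'   loading is per bp (see [smc_params()]).
#' @return An object of class `genome_spec` with fields `length`,
#'   `parS_bp` (signed bp), `parS_deg`, `parS_weight`.
#' @examples
#' g <- genome_spec(parS_deg = -59)
#' deg_to_bp(-59, g)
#' @export
genome_spec <- function(length = 4033000, parS_deg = numeric(),
                        parS_weight = 1) {
  stopifnot(is.numeric(length), length(length) == 1L, length > 0)
  if (length(parS_deg)) {
    if (any(parS_deg <= -180 | parS_deg > 180))
      stop("parS positions must lie in (-180, 180] degrees")
  }
  parS_weight <- rep_len(parS_weight, length(parS_deg))
  if (any(parS_weight < 0)) stop("parS loading weights must be >= 0")
  structure(
    list(length = as.numeric(length),
         parS_deg = as.numeric(parS_deg),
         parS_bp = vapply(parS_deg, deg_to_bp, numeric(1),
                          genome = list(length = as.numeric(length))),
         parS_weight = as.numeric(parS_weight)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> circular, %s bp, %d parS site(s)\n",
              format(x$length, big.mark = ","), length(x$parS_bp)))
  if (length(x$parS_bp))
    cat(sprintf("  parS: %s deg (weights %s)\n",
                paste(x$parS_deg, collapse = ", "),
                paste(x$parS_weight, collapse = ", ")))
  invisible(x)
}

#' Convert degrees to signed base pairs
#'
#' @param angle Angle(s) in degrees, each in \[-180, 180\]. 0 = origin,
#'   +/-180 = terminus.
#' @param genome A [genome_spec()] (or any list with a `length` field).
#' @return Signed bp position(s), rounded to integer bp.
#' @export
deg_to_bp <- function(angle, genome) {
  if (any(angle < -180 | angle > 180))
    stop("angle must lie in [-180, 180] degrees")
  round(angle / 360 * genome$length)
}

#' Convert signed base pairs to degrees
#'
#' Inverse of [deg_to_bp()] up to bp rounding.
#'
#' @param bp Signed bp position(s) in (-length/2, length/2].
#' @param genome A [genome_spec()].
#' @return Angle(s) in degrees.
#' @export
bp_to_deg <- function(bp, genome) {
  half <- genome$length / 2
  if (any(bp <= -half - 0.5 | bp > half + 0.5))
    stop("bp position outside (-length/2, length/2]")
  bp / genome$length * 360
}

#' Shortest arc distance on the circular chromosome
#'
#' @param a,b Signed bp coordinates (vectors recycle).
#' @param genome A [genome_spec()].
#' @return Non-negative distance(s) in bp, at most `length/2`.
#' @export
circular_distance <- function(a, b, genome) {
  L <- genome$length
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

#' Map signed ori-centred coordinates to linear [0, length) coordinates
#'
#' File output and binned tracks use standard 0-based half-open linear
#' coordinates with the origin at position 0; the left arm occupies the
#' upper half of the interval.
#'
#' @param x Signed bp coordinate(s).
#' @param genome A [genome_spec()].
#' @return Linear coordinate(s) in `[0, length)`.
#' @export
signed_to_linear <- function(x, genome) {
  x %% genome$length
}

#' Map linear [0, length) coordinates to signed ori-centred coordinates
#'
#' @param x Linear coordinate(s) in `[0, length)`.
#' @param genome A [genome_spec()].
#' @return Signed coordinate(s) in (-length/2, length/2].
#' @export
linear_to_signed <- function(x, genome) {
  L <- genome$length
  x <- x %% L
  ifelse(x > L / 2, x - L, x)
}

# number of bins covering the circular genome at bin_size
n_bins <- function(genome, bin_size) as.integer(ceiling(genome$length / bin_size))

# signed coordinates of bin centres (bins laid out on linear [0, L))
bin_centers_signed <- function(genome, bin_size) {
  nb <- n_bins(genome, bin_size)
  starts <- (seq_len(nb) - 1) * bin_size
  ends <- pmin(starts + bin_size, genome$length)
  linear_to_signed((starts + ends) / 2, genome)
}

# bin index (1-based) of a signed coordinate
bin_of <- function(x, genome, bin_size) {
  idx <- floor(signed_to_linear(x, genome) / bin_size) + 1L
  pmin(as.integer(idx), n_bins(genome, bin_size))
}
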