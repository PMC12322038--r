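# Plain-text interchange: bedGraph tracks, dense/sparse matrix files,
# YAML scenario configs. The circular genome is emitted as a single
# sequence on linear 0-based half-open coordinates with ori at 0.

#' Write a profile as bedGraph
#'
#' Standard bedGraph (chrom, 0-based half-open start/end, value) with the
#' genome metadata in `#` header comments. Zero bins are omitted (sparse
#' convention); an all-zero track yields a header-only file.
#'
#' @param profile A `profile1d`.
#' @param path Output file path.
#' @param chrom Sequence name (default `"chr"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, chrom = "chr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# genome_length=%d", as.integer(profile$genome$length)),
    sprintf("# bin_size=%d", as.integer(profile$bin_size)),
    sprintf("# kind=%s", profile$kind),
    sprintf("# normalization=%s", profile$normalization),
    sprintf("track type=bedGraph name=%s", profile$kind)), con)
  nb <- length(profile$values)
  starts <- (seq_len(nb) - 1) * profile$bin_size
  ends <- pmin(starts + profile$bin_size, profile$genome$length)
  keep <- profile$values != 0
  if (any(keep))
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, as.integer(starts[keep]),
                       as.integer(ends[keep]), profile$values[keep]), con)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()]
#'
#' Unlisted bins read back as zeros; overlapping intervals are an error
#' (reported with the offending line number).
#'
#' @param path File path.
#' @param genome Optional [genome_spec()]; defaults to one reconstructed
#'   from the header metadata.
#' @return A `profile1d`.
#' @export
read_bedgraph <- function(path, genome = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("missing header field: ", key)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  glen <- as.numeric(get("genome_length"))
  bin_size <- as.numeric(get("bin_size"))
  kind <- get("kind")
  norm <- get("normalization")
  if (is.null(genome)) genome <- genome_spec(length = glen)
  nb <- n_bins(genome, bin_size)
  vals <- numeric(nb)
  body_idx <- which(!grepl("^#|^track", lines) & nzchar(lines))
  seen_end <- -1
  for (li in body_idx) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4 || is.na(suppressWarnings(as.numeric(f[2]))))
      stop(sprintf("malformed bedGraph line %d", li))
    s <- as.numeric(f[2]); e <- as.numeric(f[3]); v <- as.numeric(f[4])
    if (is.na(s) || is.na(e) || is.na(v) || e <= s)
      stop(sprintf("malformed bedGraph line %d", li))
    if (s < seen_end)
      stop(sprintf("overlapping intervals at line %d", li))
    seen_end <- e
    b0 <- floor(s / bin_size) + 1
    b1 <- ceiling(e / bin_size)
    if (b1 > nb) stop(sprintf("interval beyond genome at line %d", li))
    vals[b0:b1] <- v
  }
  profile1d(vals, genome, bin_size,
            kind = match.arg(kind, c("MFA", "OCCUPANCY", "RATIO", "COUNTS")),
            normalization = norm)
}

#' Write a contact map as a dense tab-delimited matrix
#'
#' `#` header comments carry the genome length, bin size and normalization.
#'
#' @param map A `contact_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# genome_length=%d", as.integer(map$genome$length)),
    sprintf("# bin_size=%d", as.integer(map$bin_size)),
    sprintf("# normalization=%s", map$normalization)), con)
  utils::write.table(format(map$matrix, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dense contact matrix written by [write_contact_matrix()]
#'
#' @param path File path.
#' @param genome Optional [genome_spec()].
#' @return A `contact_map`.
#' @export
read_contact_matrix <- function(path, genome = NULL) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("missing header field: ", key)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  glen <- as.numeric(get("genome_length"))
  bin_size <- as.numeric(get("bin_size"))
  norm <- get("normalization")
  if (is.null(genome)) genome <- genome_spec(length = glen)
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  m <- (m + t(m)) / 2 # remove float-formatting asymmetry
  contact_map(m, genome, bin_size, normalization = norm)
}

#' Write a contact map as sparse upper-triangle triplets
#'
#' Columns `bin1`, `bin2` (1-based, bin1 <= bin2) and `value`; zero entries
#' omitted.
#'
#' @param map A `contact_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_triplets <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# genome_length=%d", as.integer(map$genome$length)),
    sprintf("# bin_size=%d", as.integer(map$bin_size)),
    sprintf("# normalization=%s", map$normalization),
    "bin1\tbin2\tvalue"), con)
  ut <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0,
              arr.ind = TRUE)
  if (nrow(ut))
    writeLines(sprintf("%d\t%d\t%.10g", ut[, 1], ut[, 2],
                       map$matrix[ut]), con)
  invisible(path)
}

#' Read sparse triplets written by [write_contact_triplets()]
#'
#' @param path File path.
#' @param genome Optional [genome_spec()].
#' @return A `contact_map`.
#' @export
read_contact_triplets <- function(path, genome = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("missing header field: ", key)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  glen <- as.numeric(get("genome_length"))
  bin_size <- as.numeric(get("bin_size"))
  if (is.null(genome)) genome <- genome_spec(length = glen)
  nb <- n_bins(genome, bin_size)
  m <- matrix(0, nb, nb)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            header = TRUE)
  for (r in seq_len(nrow(body))) {
    m[body$bin1[r], body$bin2[r]] <- body$value[r]
    m[body$bin2[r], body$bin1[r]] <- body$value[r]
  }
  contact_map(m, genome, bin_size, normalization = get("normalization"))
}

#' Write a scenario configuration as YAML
#'
#' Versioned plain-text schema carrying the genome, protocol events and
#' parameter sets of a scenario.
#'
#' @param scen A [scenario()] list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scen, path) {
  cfg <- list(
    schema_version = 1,
    name = scen$name,
    genome = list(length = scen$genome$length,
                  parS_deg = scen$genome$parS_deg,
                  parS_weight = scen$genome$parS_weight),
    protocol = list(initial_temp = scen$protocol$initial_temp,
                    events = lapply(seq_len(nrow(scen$protocol$events)),
                                    function(i) as.list(scen$protocol$events[i, ]))),
    rep_params = unclass(scen$rep_params),
    smc_params = unclass(scen$smc_params),
    sample_times = scen$sample_times,
    constitutive_loading = scen$constitutive_loading)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration written by [write_scenario_config()]
#'
#' @param path YAML file path.
#' @return A scenario list (see [scenario()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1)
    stop("unsupported config schema version")
  g <- genome_spec(length = cfg$genome$length,
                   parS_deg = unlist(cfg$genome$parS_deg),
                   parS_weight = unlist(cfg$genome$parS_weight))
  ev <- do.call(rbind, lapply(cfg$protocol$events, function(e)
    data.frame(time = e$time, kind = e$kind,
               value = if (is.null(e$value) || is.na(e$value)) NA_real_
               else e$value)))
  pr <- protocol(ev, initial_temp = cfg$protocol$initial_temp)
  rp <- do.call(replisome_params, cfg$rep_params)
  sp <- do.call(smc_params, cfg$smc_params)
  list(name = cfg$name, genome = g, protocol = pr, rep_params = rp,
       smc_params = sp, sample_times = unlist(cfg$sample_times),
       constitutive_loading = isTRUE(cfg$constitutive_loading))
}
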