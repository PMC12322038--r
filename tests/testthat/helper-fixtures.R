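# shared fixtures: a small default genome and quick parameter sets

test_genome <- function(parS_deg = -59) genome_spec(parS_deg = parS_deg)

# analytic T = 0 MFA profile for a pre-existing-fork fraction f:
# 1 + f * (1 - x / (L/2)) at distance x from ori
analytic_t0_profile <- function(f, genome, bin_size = 10000) {
  ctr <- abs(smcollide:::bin_centers_signed(genome, bin_size))
  profile1d(1 + f * (1 - ctr / (genome$length / 2)), genome, bin_size,
            kind = "MFA", normalization = "copy_number")
}

# barrier list for a single static fork pair at +/- pos in every cell
static_barriers <- function(n_cells, pos, genome) {
  fork_barriers(data.frame(cell = seq_len(n_cells), initiated = TRUE,
                           left_pos = -pos, right_pos = pos,
                           left_stalled = TRUE, right_stalled = TRUE,
                           completed = FALSE), genome)
}

no_barriers <- function(n_cells, genome) {
  fork_barriers(data.frame(cell = seq_len(n_cells), initiated = FALSE,
                           left_pos = 0, right_pos = 0,
                           left_stalled = FALSE, right_stalled = FALSE,
                           completed = FALSE), genome)
}
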