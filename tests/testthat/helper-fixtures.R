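# Shared fixtures: a reduced-scale simulation config for tests that do not
# need the full cohort geometry, and the printed progeny table used
# throughout (31 horned F, 14 polled F, 29 horned M, 2 polled M).

small_cfg <- function(seed = 1, n_junction_fragments = 40L,
                      n_background_pairs = 50L, ...) {
  simulation_config(
    seed = seed,
    n_markers = 600L,
    chrom_length = 2e7,
    deletion_start_flank = 8e6,
    deletion_end_flank = 8.6e6,
    depth_window_bp = 10000L,
    n_junction_fragments = n_junction_fragments,
    n_background_pairs = n_background_pairs,
    ...
  )
}

recorded_birth_counts <- function() {
  transmission_counts("birth", c(M.del = 2L, M.wt = 29L,
                                 F.del = 14L, F.wt = 31L))
}

# deterministic random reference over one window, for junction tests that
# construct their own clipped reads
random_reference_fetch <- function(origin, length, seed = 99) {
  set.seed(seed)
  seqc <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                collapse = "")
  function(start, end) {
    stopifnot(start >= origin, end <= origin + length - 1)
    substr(seqc, start - origin + 1, end - origin + 1)
  }
}
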