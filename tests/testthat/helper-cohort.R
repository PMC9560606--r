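# Shared fixtures: configurations scaled for test speed and a cached small
# cohort. Everything is generated in code under fixed seeds.

# Small genome / few noise sites; all other parameters at package defaults
# unless overridden.
fast_config <- function(...) {
  overrides <- list(...)
  defaults <- list(genome_size = 2e5, n_genes = 20, n_noise_sites = 20,
                   seed = 101L)
  do.call(cohort_config, utils::modifyList(defaults, overrides))
}

# Noise-free deep configuration: VAFs bounded away from zero, deep depth,
# negligible error, no oxoG artifacts. Used for exact-recovery tests of the
# classification logic (not of detectability limits).
clean_config <- function(...) {
  fast_config(
    depth_mean = 3000, seq_error_rate = 1e-9, oxog_rate = 0,
    vaf_params = list(early = c(mean = 0.10, sd = 0.02),
                      late = c(mean = 0.10, sd = 0.02),
                      tumor = c(mean = 0.20, sd = 0.03)),
    ...)
}

clean_params <- function() {
  caller_params(error_rate = 1e-9)
}

# One modest cohort reused across test files (computed once per test run).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(fast_config(n_individuals = 6, seed = 202L))
    }
    cache
  }
})

# Build an observation row set by hand.
make_obs <- function(tissue_id, individual, pos, alt_count, depth = 500,
                     ref = "C", alt = "T", f1r2 = NULL, contig = "chr1") {
  n <- max(length(pos), length(alt_count))
  pos <- rep_len(pos, n); alt_count <- rep_len(alt_count, n)
  depth <- rep_len(depth, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (is.null(f1r2)) f1r2 <- alt_count %/% 2
  f1r2 <- rep_len(f1r2, n)
  data.frame(tissue_id = tissue_id, individual = individual,
             contig = contig, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_count = alt_count, alt_f1r2 = f1r2,
             alt_f2r1 = alt_count - f1r2, vaf = alt_count / depth,
             stringsAsFactors = FALSE)
}
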