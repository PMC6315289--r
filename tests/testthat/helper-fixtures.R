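# Shared fixtures, built in code at test time.

tiny_counts <- function() {
  m <- matrix(c(100, 200, 10, 20), nrow = 2, byrow = TRUE,
              dimnames = list(c("geneA", "geneB"), c("cell1", "cell2")))
  storage.mode(m) <- "double"
  m
}

tiny_cells <- function(ids = c("cell1", "cell2"),
                       times = c(0, 48),
                       reads = c(7e6, 7e6)) {
  data.frame(cell_id = ids, capture_time_h = times, mapped_reads = reads,
             stringsAsFactors = FALSE)
}

quick_config <- function(...) {
  args <- list(kl_direction = "symmetrized", mcmc_warmup = 80L, mcmc_draws = 80L,
               n_analysis_genes = 20L, n_permutations = 99L)
  args[names(list(...))] <- list(...)
  do.call(run_config, args)
}

small_sim <- function(seed = 7L, ...) {
  simulate_expression(sim_config(n_cells_per_group = 12L, n_down = 10L,
                                 n_up = 10L, n_flat = 15L, seed = seed, ...))
}

# brute-force half-open overlap used as the interval-engine oracle
overlaps_oracle <- function(intervals, region) {
  if (nrow(intervals) == 0L) return(FALSE)
  any(intervals$chrom == region$chrom &
        intervals$start < region$end &
        region$start < intervals$end)
}
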