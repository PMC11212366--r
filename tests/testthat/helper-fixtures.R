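# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

introscape_test_cache <- function() .fixture_cache

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small two-chromosome study with planted tracts
small_study <- function() cached("small_study", {
  simulate_study(sim_config(seed = 101,
                            chromosome_lengths = c(chr1 = 2e5, chr2 = 15e4),
                            tract_count = 3, gene_count = 40,
                            family_gene_count = 4, psg_fraction = 0.15))
})

# truth labels for the SNV sites of an alignment
truth_labels <- function(aln, tracts) {
  lab <- rep(FALSE, length(aln$pos))
  for (i in seq_len(nrow(tracts)))
    lab[aln$chrom == tracts$chrom[i] & aln$pos >= tracts$start[i] &
          aln$pos < tracts$end[i]] <- TRUE
  lab
}

# hand-built posterior track
toy_track <- function(pos, post, chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), posterior = post)
}

# uniform depth windows covering a genome
flat_depth <- function(genome, value = 25, window = 10000L) {
  out <- lapply(names(genome), function(cc) {
    starts <- seq(0L, genome[[cc]] - 1L, by = window)
    data.table::data.table(chrom = cc, start = starts,
                           end = pmin(starts + window, genome[[cc]]),
                           depth_O = value, depth_P = value,
                           depth_D = value, depth_F = value)
  })
  data.table::rbindlist(out)
}

random_params <- function() {
  hmm_params(gamma = runif(1, 0.01, 0.3), alpha = runif(1, 0.01, 0.3),
             t_term = runif(1, 0.01, 0.2), t_minor = runif(1, 0.001, 0.05),
             delta = runif(1, 0.001, 0.1))
}

random_column <- function(p_missing = 0.2) {
  x <- sample(c(BASES4, NA), 4, replace = TRUE,
              prob = c(rep((1 - p_missing) / 4, 4), p_missing))
  setNames(x, c("O", "P", "D", "F"))
}
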