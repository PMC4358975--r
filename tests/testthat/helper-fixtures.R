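# Small in-code fixtures shared across test files.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Draw binomial read counts for n mutations at true VAF p and mean depth.
make_read_counts <- function(n, p, depth = 105, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- pmax(stats::rpois(n, depth), 1L)
  a <- stats::rbinom(n, d, p)
  data.frame(id = sprintf("m%04d", seq_len(n)),
             ref_count = d - a, alt_count = a)
}

# A compact genome and rate that give a few hundred mutations per tumor:
# fast enough for repeated simulation, dense enough for recovery checks.
test_config <- function(seed, alpha, events = list(), subclones = list(),
                        lambda_rate = 20, het_density = 0.2, scale = 0.05) {
  sim_config(seed = seed, alpha = alpha, lambda_rate = lambda_rate,
             genome = sim_genome(scale = scale), events = events,
             subclones = subclones, het_density = het_density)
}
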