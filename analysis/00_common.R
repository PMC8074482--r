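## Shared setup for the analysis drivers: seed, output directory, and the
## simulated experiment every later stage reads. Each driver can be run on
## its own; stages re-simulate deterministically rather than depending on
## files written by earlier stages.
library(chronoseq)

SEED <- as.integer(Sys.getenv("CHRONOSEQ_SEED", "1"))
RESULTS <- Sys.getenv("CHRONOSEQ_RESULTS", "results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

load_experiment <- function() {
  sim <- simulate_experiment(fixture_config(), seed = SEED)
  pre <- preprocess_counts(sim$counts)
  list(sim = sim, pre = pre)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
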