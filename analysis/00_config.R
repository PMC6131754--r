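# Shared settings for the analysis scripts. Each numbered script is a thin
# driver over the enhancerReprog package: it rebuilds the (deterministic)
# reference scenario, runs one stage, prints what it found and writes its
# tables under results/.

library(enhancerReprog)

ANALYSIS_SEED <- 20260926L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Reference scenario: the observed human-side category mix (2% functionally
# conserved / 42% reprogrammed / 56% gained), four paired tissues, ~1 kb
# enhancers, a 1.4-fold planted expression shift.
reference_config <- function() scenario_config(seed = ANALYSIS_SEED)

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
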