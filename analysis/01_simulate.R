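#!/usr/bin/env Rscript
# Build the two-species reference scenario and export it as standard files
# (FASTA genomes, alignment chain, per-tissue BED, MEME motifs, expression
# TSV) together with the planted truth tables.

source("analysis/00_config.R")

bundle <- simulate_scenario(reference_config(),
                            out_dir = file.path(RESULTS_DIR, "data"))

message("genomes: ", length(bundle$genomes$a), " sequences per species, ",
        sum(bundle$seq_lengths$a), " bp (species A)")
tab <- table(bundle$truth$category[!bundle$truth$b_only])
message("planted categories: ", paste(names(tab), tab, collapse = ", "))
message("planted binding sites: ", nrow(bundle$motif_truth))
write_tsv(as.data.frame(tab), "01_planted_categories.tsv")
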