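#!/usr/bin/env Rscript
# Expression consequences of reprogramming in the reference scenario:
# per-reprogramming-set shift tests (novel vs source tissue in each
# species), gene-locus bins by enhancer count, and the single-enhancer
# locus (seLoci) category make-up.

source("analysis/00_config.R")

bundle <- simulate_scenario(reference_config())

shifts <- expression_shift_analysis(bundle)
message("expression shifts per reprogramming set:")
print(shifts)
message(sprintf("concordant sets: %d/%d (%.0f%%)", sum(shifts$concordant),
                nrow(shifts), 100 * mean(shifts$concordant)))
write_tsv(shifts, "04_expression_shift.tsv")

cl <- classify_genome_wide(bundle$records_a, bundle$bed_b, bundle$chains)
bins <- bin_by_enhancer_count(bundle$loci, cl, bundle$expression$a,
                              tissue = bundle$tissues[1])
print(bins)
write_tsv(bins, "04_locus_bins.tsv")

sel <- seloci_test(bundle$loci, cl)
if (!is.null(sel)) {
  message("single-enhancer locus category make-up:")
  print(sel)
  write_tsv(sel, "04_seloci.tsv")
}
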