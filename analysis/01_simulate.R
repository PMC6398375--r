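#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known truth.
#
# Sequence side: 120 ortholog triplets on the ((HCAR, HMAC), HFLA) topology
# with mostly purifying selection, a small positively selected class, and a
# 5% paralog-contaminant class with inflated synonymous divergence.
# Expression side: a gene x sample NB count matrix for 8 + 17 + 11 samples
# with species effects and the vitellogenin-like outlier subgroup in half
# of the HFLA individuals.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

sim <- simulate_dataset(CFG$sim)
write_sim_dataset(sim, DATA_DIR)
message(sprintf("simulated %d triplets (%d contaminated by paralogs)",
                nrow(sim$truth), sum(sim$truth$is_paralog)))
message(sprintf("true omega classes: %s",
                paste(names(table(sim$truth$omega_class)),
                      table(sim$truth$omega_class), collapse = ", ")))

cs <- do.call(simulate_counts, CFG$sim_counts)
write_counts(cs$counts, file.path(DATA_DIR, "counts.tsv"))
write_sample_meta(cs$meta, file.path(DATA_DIR, "samples.tsv"))
truth <- cs$truth
write.table(truth, file.path(DATA_DIR, "counts_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(cs$outlier_samples, file.path(DATA_DIR, "outlier_samples.txt"))
message(sprintf("simulated counts: %d genes x %d samples, %d marker genes, %d outlier samples",
                nrow(cs$counts), ncol(cs$counts), sum(truth$is_marker),
                length(cs$outlier_samples)))
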