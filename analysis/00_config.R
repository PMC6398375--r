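# Shared settings for the analysis drivers. Each numbered script sources
# this file, reads its inputs from results/, and writes its outputs there,
# so the chain can be re-run stage by stage:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_orthologs.R
#   Rscript analysis/03_selection.R
#   Rscript analysis/04_expression.R

library(orthoselect)

SEED <- 1
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")

CFG <- default_config(SEED)
CFG$sim <- sim_params(n_genes = 120, seed = SEED)

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(d, name) {
  path <- file.path(RESULTS, name)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
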