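#!/usr/bin/env Rscript
# Stage 4: expression. Median-of-ratios normalisation, NB likelihood-ratio
# DE across the three species, pairwise contrasts, Manhattan-distance PCoA,
# the marker-based outlier screen, the vitellogenin-style rerun excluding
# flagged samples, and signed-log-p GO enrichment for one contrast.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

counts <- read_counts(file.path(DATA_DIR, "counts.tsv"))
meta <- read_sample_meta(file.path(DATA_DIR, "samples.tsv"))
truth <- read.table(file.path(DATA_DIR, "counts_truth.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
stopifnot(identical(colnames(counts), meta$sample_id))

sf <- size_factors(counts)
de <- nb_lrt(counts, meta$species, sf)
write_tsv(de, "de_lrt.tsv")
message(sprintf("LRT: %d/%d genes DE at p < %.2f (true DE fraction %.2f)",
                sum(de$p_value < CFG$de$p_threshold), nrow(counts),
                CFG$de$p_threshold, mean(!truth$null)))

tr <- transform_counts(counts, sf)
pc <- pcoa_manhattan(tr)
write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                     species = meta$species, pc$coordinates), "pcoa.tsv")
message(sprintf("PCoA: axis 1 = %.1f%%, axis 2 = %.1f%% of retained variance",
                pc$pct_variance[1], pc$pct_variance[2]))

species_pairs <- combn(unique(meta$species), 2, simplify = FALSE)
deg <- function(ct) sum(bh_fdr(ct$p_value, CFG$de$fdr)$significant)
contrasts <- lapply(species_pairs, function(pr)
  contrast(counts, meta$species, pr[1], pr[2], sf))
names(contrasts) <- vapply(species_pairs, paste, "", collapse = "_")
for (nm in names(contrasts)) write_tsv(contrasts[[nm]],
                                       paste0("contrast_", nm, ".tsv"))

markers <- truth$gene_id[truth$is_marker]
screen <- marker_outlier_screen(counts, meta, markers,
                                threshold = CFG$marker$threshold, sf)
planted <- readLines(file.path(DATA_DIR, "outlier_samples.txt"))
message(sprintf("marker screen: flagged %s (planted: %s)",
                paste(screen$flagged, collapse = ","),
                paste(planted, collapse = ",")))

keep <- !meta$sample_id %in% screen$flagged
sf2 <- size_factors(counts[, keep])
contrasts2 <- lapply(species_pairs, function(pr)
  contrast(counts[, keep], meta$species[keep], pr[1], pr[2], sf2))
names(contrasts2) <- names(contrasts)
cmp <- data.frame(contrast = names(contrasts),
                  deg_all_samples = vapply(contrasts, deg, 1),
                  deg_outliers_excluded = vapply(contrasts2, deg, 1))
write_tsv(cmp, "deg_counts.tsv")
message("DEG counts at FDR 10% before/after excluding flagged samples:")
for (i in seq_len(nrow(cmp)))
  message(sprintf("  %s: %d -> %d", cmp$contrast[i], cmp$deg_all_samples[i],
                  cmp$deg_outliers_excluded[i]))

# signed log-p enrichment input from the HCAR vs HFLA contrast
ct <- contrasts2[["HCAR_HFLA"]]
slp <- setNames(signed_logp(ct$p_value, ct$log2fc), ct$gene_id)
go <- simulate_go(ct$gene_id, n_terms = CFG$go$n_terms,
                  genes_per_term = CFG$go$genes_per_term,
                  planted = CFG$go$planted, seed = CFG$go$seed + 1)
shifted <- apply_planted_effects(slp, go$truth)
enr <- do.call(rbind, lapply(c("BP", "CC", "MF"), function(dm)
  run_enrichment(shifted, go$annotation, dm, fdr = CFG$go$fdr,
                 min_size = CFG$go$min_size)))
write_tsv(enr, "enrichment_expression.tsv")
message(sprintf("GO enrichment (expression): %d significant terms at FDR %.0f%%",
                sum(enr$significant), 100 * CFG$go$fdr))
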