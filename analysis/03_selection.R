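#!/usr/bin/env Rscript
# Stage 3: selection scan over the retained orthologs. Pairwise NG86 dN/dS
# for the three species comparisons, the 4-component mixture filter on
# omega > 1 that removes the unrealistically high component, the bounded
# positive-selection call (1 < omega < 3), and rank-based GO enrichment of
# the omega measure per domain at FDR 10%.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

groups <- read.table(file.path(RESULTS, "groups.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
retained <- groups[groups$retained, ]
cds <- lapply(c(HCAR = "HCAR", HMAC = "HMAC", HFLA = "HFLA"), function(sp)
  as.list(read_fasta(file.path(DATA_DIR, paste0(sp, "_cds.fasta")),
                     "nucleotide")))

dnds <- dnds_table(retained, cds)
write_tsv(dnds, "dnds.tsv")
ok <- dnds$status == "ok"
message(sprintf("dN/dS: %d pairs, %d with defined omega, %d (%.1f%%) with omega > 1",
                nrow(dnds), sum(ok), sum(dnds$omega > 1, na.rm = TRUE),
                100 * mean(dnds$omega[ok] > 1)))

pos_rows <- list()
for (pr in unique(dnds$pair)) {
  d <- dnds[dnds$pair == pr & ok, ]
  om <- setNames(d$omega, d$gene_a)
  res <- omega_outlier_filter(om, k = CFG$omega_filter$k,
                              seed = CFG$omega_filter$seed)
  boundary <- if (is.na(res$boundary)) "no mixture fit"
              else sprintf("boundary %.2f", res$boundary)
  message(sprintf("%s: %d genes with omega > 1, %d positively selected (%s)",
                  pr, sum(om > 1), length(res$positive), boundary))
  if (length(res$positive) > 0)
    pos_rows[[pr]] <- data.frame(pair = pr, gene = res$positive,
                                 omega = unname(om[res$positive]),
                                 stringsAsFactors = FALSE)
}
positive <- if (length(pos_rows)) do.call(rbind, pos_rows) else
  data.frame(pair = character(), gene = character(), omega = numeric())
write_tsv(positive, "positively_selected.tsv")

# GO enrichment on the mean omega per reference gene; the simulated
# annotation plants one enriched term whose members get shifted omega
measure <- tapply(dnds$omega[ok], dnds$gene_a[ok], mean)
measure <- setNames(as.numeric(measure), names(measure))
go <- simulate_go(names(measure), n_terms = CFG$go$n_terms,
                  genes_per_term = CFG$go$genes_per_term,
                  planted = CFG$go$planted, seed = CFG$go$seed)
write_go(go$annotation, file.path(RESULTS, "go_annotation.tsv"))
shifted <- apply_planted_effects(measure, go$truth)
enr <- do.call(rbind, lapply(c("BP", "CC", "MF"), function(dm)
  run_enrichment(shifted, go$annotation, dm, fdr = CFG$go$fdr,
                 min_size = CFG$go$min_size)))
write_tsv(enr, "enrichment_dnds.tsv")
message(sprintf("GO enrichment (dN/dS): %d significant terms at FDR %.0f%%; planted term %s recovered: %s",
                sum(enr$significant), 100 * CFG$go$fdr, go$truth$term[1],
                go$truth$term[1] %in% enr$term[enr$significant]))
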