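#!/usr/bin/env Rscript
# Stage 2: ortholog calling. All-vs-all protein search over the three
# proteomes, three-way reciprocal best hits against the HMAC reference
# (e-value < 1e-5, identity > 75%, alignment > 50% of the subject), NG86
# synonymous divergence per candidate group, the 3-component dS mixture
# filter that removes the highest-mean (false-positive) component, Markov
# clustering of the similarity graph, and the concordance intersection.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

cds <- lapply(c(HCAR = "HCAR", HMAC = "HMAC", HFLA = "HFLA"), function(sp)
  read_fasta(file.path(DATA_DIR, paste0(sp, "_cds.fasta")), "nucleotide"))
proteomes <- lapply(cds, function(ss)
  vapply(names(ss), function(id) translate_and_validate(ss[[id]], id),
         character(1)))

message("computing all-vs-all hit tables (this is the slow step)")
hits <- hit_tables(proteomes, CFG$hit$report_threshold)
for (nm in names(hits))
  write_hits(hits[[nm]], file.path(RESULTS, paste0("hits_", nm, ".tsv")))

cand <- reciprocal_best_triplets(hits, lapply(proteomes, nchar),
                                 reference = CFG$reference,
                                 max_evalue = CFG$hit$max_evalue,
                                 min_identity = CFG$hit$min_identity,
                                 min_coverage = CFG$hit$min_coverage)
message(sprintf("RBB candidates: %d of %d simulated genes", nrow(cand),
                CFG$sim$n_genes))

cand_dnds <- dnds_table(cand, lapply(cds, as.list))
write_tsv(cand_dnds, "candidate_dnds.tsv")

mean_ds <- tapply(cand_dnds$dS, rep(seq_len(nrow(cand)), each = 3),
                  mean, na.rm = TRUE)
ds_res <- ds_false_positive_filter(as.numeric(mean_ds),
                                   k = CFG$ds_filter$k,
                                   seed = CFG$ds_filter$seed)
message(sprintf("dS filter: dropped %d groups (%.1f%%), component means %s",
                sum(!ds_res$keep), 100 * ds_res$dropped_fraction,
                paste(sprintf("%.3f", ds_res$model$means), collapse = " / ")))

graph <- build_similarity_graph(hits, unlist(lapply(proteomes, names),
                                             use.names = FALSE))
clusters <- mcl_cluster(graph, inflation = CFG$mcl$inflation)
message(sprintf("MCL: %d clusters over %d genes",
                length(unique(clusters)), length(clusters)))

conc <- concordance_filter(cand, ds_res$keep, clusters)
write_tsv(conc$groups, "groups.tsv")
message(sprintf("concordance: retained %d/%d candidates (%.1f%%)",
                sum(conc$groups$retained), nrow(cand),
                100 * conc$retention_fraction))

truth <- read.table(file.path(DATA_DIR, "truth.tsv"), sep = "\t",
                    header = TRUE)
called <- sub("HMAC_", "", conc$groups$HMAC[conc$groups$retained])
clean <- truth$gene[!truth$is_paralog]
message(sprintf("truth check: recall of clean triplets %.3f; contaminants retained %d",
                mean(clean %in% called),
                sum(truth$gene[truth$is_paralog] %in% called)))
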