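# Orchestration: a single configuration object whose defaults are the
# pipeline's canonical thresholds (hit acceptance 1e-5 / 75% / 50%, mixture
# orders 3 and 4, positive-selection bounds (1, 3), GO FDR 0.10, DE p 0.01)
# and a run_all() that chains simulate -> align -> orthologs -> dS filter ->
# dN/dS -> omega filter -> enrichment, plus the expression branch
# counts -> DE -> contrasts -> signed log-p -> enrichment -> PCoA with the
# marker-based outlier exclusion rerun.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Nested list of all stage parameters.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    sim = sim_params(n_genes = 120, seed = seed),
    sim_counts = list(n_genes = 1500, de_fraction = 0.1,
                      outlier_subgroup = TRUE, seed = seed + 1),
    hit = list(max_evalue = 1e-5, min_identity = 75, min_coverage = 0.5,
               report_threshold = 1e-3),
    reference = "HMAC",
    mcl = list(inflation = 1.5),
    ds_filter = list(k = 3, seed = seed + 2),
    omega_filter = list(k = 4, seed = seed + 3,
                        lower = 1, upper = 3),
    go = list(n_terms = 30, genes_per_term = 20,
              planted = c(T01 = 1.5), seed = seed + 4,
              fdr = 0.10, min_size = 5),
    de = list(p_threshold = 0.01, fdr = 0.10),
    marker = list(threshold = 2))
}

ordered_pair_names <- function(species = SPECIES3) {
  prs <- expand.grid(q = species, s = species, stringsAsFactors = FALSE)
  prs <- prs[prs$q != prs$s, ]
  paste0(prs$q, "_", prs$s)
}

#' All-vs-all hit tables for the six ordered species pairs
#'
#' Alignments are computed once per unordered proteome pair and both
#' directions' statistics are derived from them.
#'
#' @param proteomes Named list (per species) of named protein vectors.
#' @param report_threshold E-value reporting cutoff.
#' @return Named list of hit tables, names like `"HCAR_HMAC"`.
#' @export
hit_tables <- function(proteomes, report_threshold = 1e-3) {
  species <- names(proteomes)
  hits <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    a <- species[i]; b <- species[j]
    both <- all_vs_all_both(proteomes[[a]], proteomes[[b]], report_threshold)
    hits[[paste0(a, "_", b)]] <- both$ab
    hits[[paste0(b, "_", a)]] <- both$ba
  }
  hits
}

#' Pairwise dN/dS table for retained ortholog groups
#'
#' For each group, NG86 divergence for the three species pairs.
#'
#' @param groups `data.frame` with one gene-id column per species.
#' @param cds Named list (per species) of named CDS vectors.
#' @return `data.frame`: `pair` (AB/AC/BC label built from species names),
#'   gene ids, `aligned_codons`, `N`, `S`, `Nd`, `Sd`, `dN`, `dS`, `omega`,
#'   `status`.
#' @export
dnds_table <- function(groups, cds) {
  species <- intersect(SPECIES3, names(groups))
  combos <- combn(species, 2, simplify = FALSE)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    for (cb in combos) {
      ida <- groups[[cb[1]]][g]
      idb <- groups[[cb[2]]][g]
      div <- ng86_cds(cds[[cb[1]]][[ida]], cds[[cb[2]]][[idb]],
                      ids = c(ida, idb))
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste0(cb[1], "_", cb[2]), gene_a = ida, gene_b = idb,
        aligned_codons = div$aligned_codons, N = div$N, S = div$S,
        Nd = div$Nd, Sd = div$Sd, dN = div$dN, dS = div$dS,
        omega = div$omega, status = div$status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on simulated data
#'
#' Executes the sequence stage (simulate, align, reciprocal-best-hit
#' triplets, dS mixture filter, Markov-cluster concordance, NG86 dN/dS,
#' high-omega filter, bounded positive-selection call, GO enrichment on the
#' omega measure) and the expression stage (simulated counts, NB LRT,
#' pairwise contrasts, signed log-p enrichment input, Manhattan PCoA,
#' marker outlier screen with contrast rerun), and returns a stage-count
#' report with all intermediate tables.
#'
#' @param config Configuration from [default_config()].
#' @param outdir Optional directory; when given, intermediate TSVs and the
#'   resolved configuration are written there.
#' @return List of class `pipeline_report`; see `summary` element for the
#'   per-stage counts.
#' @export
run_all <- function(config = default_config(), outdir = NULL) {
  log_stage <- function(...) message("[run_all] ", sprintf(...))

  # --- sequence stage -------------------------------------------------
  log_stage("simulating %d ortholog triplets", config$sim$n_genes)
  sim <- simulate_dataset(config$sim)
  cds <- lapply(sim$fasta, as.list)
  proteomes <- lapply(sim$fasta, function(ss)
    vapply(names(ss), function(id) translate_and_validate(ss[[id]], id),
           character(1)))

  log_stage("computing all-vs-all hit tables")
  hits <- hit_tables(proteomes, config$hit$report_threshold)
  lens <- lapply(proteomes, nchar)

  log_stage("calling reciprocal-best-hit triplets (reference %s)",
            config$reference)
  candidates <- reciprocal_best_triplets(
    hits, lens, reference = config$reference,
    max_evalue = config$hit$max_evalue,
    min_identity = config$hit$min_identity,
    min_coverage = config$hit$min_coverage)

  log_stage("NG86 divergence for %d candidate groups", nrow(candidates))
  cand_dnds <- dnds_table(candidates, cds)
  mean_ds <- tapply(cand_dnds$dS,
                    rep(seq_len(nrow(candidates)), each = 3),
                    function(x) mean(x, na.rm = TRUE))
  ds_res <- ds_false_positive_filter(as.numeric(mean_ds),
                                     k = config$ds_filter$k,
                                     seed = config$ds_filter$seed)

  log_stage("Markov clustering")
  graph <- build_similarity_graph(hits, unlist(lapply(proteomes, names),
                                               use.names = FALSE))
  clusters <- mcl_cluster(graph, inflation = config$mcl$inflation)

  conc <- concordance_filter(candidates, ds_res$keep, clusters)
  retained <- conc$groups[conc$groups$retained, ]
  log_stage("%d/%d groups retained by concordance", nrow(retained),
            nrow(candidates))

  ret_dnds <- cand_dnds[rep(conc$groups$retained, each = 3), ]

  # omega filter per pairwise comparison
  positive <- character(0)
  omega_models <- list()
  for (pr in unique(ret_dnds$pair)) {
    d <- ret_dnds[ret_dnds$pair == pr & ret_dnds$status == "ok", ]
    om <- setNames(d$omega, d$gene_a)
    res <- omega_outlier_filter(om, k = config$omega_filter$k,
                                seed = config$omega_filter$seed)
    omega_models[[pr]] <- res
    positive <- union(positive, paste0(pr, ":", res$positive))
  }
  n_omega_gt1 <- sum(ret_dnds$omega > 1, na.rm = TRUE)

  # GO enrichment over mean omega per reference gene
  ok <- ret_dnds$status == "ok"
  omega_measure <- tapply(ret_dnds$omega[ok],
                          rep(retained$ref_gene, each = 3)[ok], mean)
  omega_measure <- setNames(as.numeric(omega_measure), names(omega_measure))
  go <- simulate_go(names(omega_measure), n_terms = config$go$n_terms,
                    genes_per_term = config$go$genes_per_term,
                    planted = config$go$planted, seed = config$go$seed)
  omega_shifted <- apply_planted_effects(omega_measure, go$truth)
  enrich_dnds <- do.call(rbind, lapply(c("BP", "CC", "MF"), function(dm)
    run_enrichment(omega_shifted, go$annotation, dm, fdr = config$go$fdr,
                   min_size = config$go$min_size)))

  # --- expression stage -----------------------------------------------
  log_stage("simulating counts and running the expression stage")
  csim <- do.call(simulate_counts, config$sim_counts)
  sf <- size_factors(csim$counts)
  de <- nb_lrt(csim$counts, csim$meta$species, sf)
  tr <- transform_counts(csim$counts, sf)
  pcoa <- pcoa_manhattan(tr)

  contrasts <- list()
  for (cb in combn(unique(csim$meta$species), 2, simplify = FALSE)) {
    key <- paste0(cb[1], "_", cb[2])
    contrasts[[key]] <- contrast(csim$counts, csim$meta$species,
                                 cb[1], cb[2], sf)
  }

  markers <- csim$truth$gene_id[csim$truth$is_marker]
  screen <- if (length(markers) > 0)
    marker_outlier_screen(csim$counts, csim$meta, markers,
                          threshold = config$marker$threshold, sf)
  else list(flagged = character(0), scores = NULL)

  contrasts_excl <- NULL
  if (length(screen$flagged) > 0) {
    keep <- !csim$meta$sample_id %in% screen$flagged
    counts2 <- csim$counts[, keep, drop = FALSE]
    sf2 <- size_factors(counts2)
    contrasts_excl <- list()
    for (cb in combn(unique(csim$meta$species), 2, simplify = FALSE)) {
      key <- paste0(cb[1], "_", cb[2])
      contrasts_excl[[key]] <- contrast(counts2, csim$meta$species[keep],
                                        cb[1], cb[2], sf2)
    }
  }

  deg_count <- function(ct) sum(bh_fdr(ct$p_value, config$de$fdr)$significant)
  # signed log-p enrichment for one contrast, over the expression GO truth
  first_ct <- contrasts[[1]]
  slp <- setNames(signed_logp(first_ct$p_value, first_ct$log2fc),
                  first_ct$gene_id)
  go_expr <- simulate_go(first_ct$gene_id, n_terms = config$go$n_terms,
                         genes_per_term = config$go$genes_per_term,
                         planted = config$go$planted,
                         seed = config$go$seed + 1)
  slp_shifted <- apply_planted_effects(slp, go_expr$truth)
  enrich_expr <- do.call(rbind, lapply(c("BP", "CC", "MF"), function(dm)
    run_enrichment(slp_shifted, go_expr$annotation, dm, fdr = config$go$fdr,
                   min_size = config$go$min_size)))

  summary <- list(
    n_genes_simulated = config$sim$n_genes,
    n_candidates = nrow(candidates),
    n_ds_dropped = sum(!ds_res$keep),
    n_retained = nrow(retained),
    retention_fraction = conc$retention_fraction,
    n_omega_gt1 = n_omega_gt1,
    n_positive_selected = length(positive),
    n_go_significant = sum(enrich_dnds$significant),
    n_deg_lrt = sum(de$p_value < config$de$p_threshold),
    deg_per_contrast = vapply(contrasts, deg_count, numeric(1)),
    deg_per_contrast_excluded =
      if (is.null(contrasts_excl)) NULL
      else vapply(contrasts_excl, deg_count, numeric(1)),
    n_flagged_samples = length(screen$flagged),
    pcoa_pct_axis1 = pcoa$pct_variance[1],
    pcoa_pct_axis2 = if (length(pcoa$pct_variance) > 1)
      pcoa$pct_variance[2] else NA_real_)

  report <- structure(list(
    config = config, sim_truth = sim$truth, candidates = candidates,
    candidate_dnds = cand_dnds, ds_filter = ds_res, clusters = clusters,
    concordance = conc, retained_dnds = ret_dnds,
    omega_models = omega_models, positive = positive,
    enrichment_dnds = enrich_dnds, counts_sim = csim, de = de,
    contrasts = contrasts, contrasts_excluded = contrasts_excl,
    screen = screen, pcoa = pcoa, enrichment_expression = enrich_expr,
    summary = summary), class = "pipeline_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a pipeline report's tables to a directory
#' @param report A `pipeline_report`.
#' @param outdir Output directory (created if needed).
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(report$concordance$groups, "groups.tsv")
  wt(report$retained_dnds, "dnds.tsv")
  wt(report$enrichment_dnds, "enrich_dnds.tsv")
  wt(report$de, "de_lrt.tsv")
  for (key in names(report$contrasts))
    wt(report$contrasts[[key]], paste0("contrast_", key, ".tsv"))
  wt(data.frame(sample_id = rownames(report$pcoa$coordinates),
                report$pcoa$coordinates), "pcoa.tsv")
  s <- report$summary
  flat <- unlist(s[!vapply(s, is.null, logical(1))])
  wt(data.frame(key = names(flat), value = as.numeric(flat)), "summary.tsv")
  dput(report$config, file.path(outdir, "config_resolved.R"))
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("pipeline report\n")
  cat(sprintf("  candidate triplets:     %d\n", s$n_candidates))
  cat(sprintf("  dropped by dS filter:   %d\n", s$n_ds_dropped))
  cat(sprintf("  retained (concordance): %d (%.1f%%)\n", s$n_retained,
              100 * s$retention_fraction))
  cat(sprintf("  omega > 1 comparisons:  %d\n", s$n_omega_gt1))
  cat(sprintf("  positively selected:    %d\n", s$n_positive_selected))
  cat(sprintf("  significant GO terms:   %d\n", s$n_go_significant))
  cat(sprintf("  DEGs (LRT p < %.2f):    %d\n", x$config$de$p_threshold,
              s$n_deg_lrt))
  cat(sprintf("  flagged outlier samples: %d\n", s$n_flagged_samples))
  cat(sprintf("  PCoA axis 1/2 variance: %.1f%% / %.1f%%\n",
              s$pcoa_pct_axis1, s$pcoa_pct_axis2))
  invisible(x)
}
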