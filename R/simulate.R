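# Synthetic-data generators: codon triplets evolved on the fixed topology
# ((HCAR, HMAC), HFLA) under a per-gene dN/dS, paralog contaminants with
# elevated synonymous divergence, GO assignments with planted enrichment
# effects, and negative-binomial count matrices with species effects and an
# optional reproductive-marker outlier subgroup.
#
# Selection is implemented as proposal thinning rather than a full codon
# rate matrix: mutation events arrive as a Poisson process over nucleotide
# sites, each proposing a uniform alternative base; proposals that create a
# stop codon are rejected; for omega <= 1 synonymous proposals are always
# accepted and nonsynonymous ones with probability omega, for omega > 1
# nonsynonymous proposals are always accepted and synonymous ones with
# probability 1/omega. The expected nonsynonymous/synonymous rate ratio is
# omega by construction, which is the oracle the estimator tests rely on.
# Branch lengths are in expected synonymous substitutions per synonymous
# site (with the default mu = 1 proposal per site per unit length, a branch
# of length t yields expected dS = t for omega <= 1 and t/omega otherwise).

#' Draw a random in-frame CDS of sense codons
#'
#' @param n_codons Number of codons.
#' @return CDS string with no stop codons.
#' @export
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Evolve a CDS along one branch; returns the descendant plus proposal /
# acceptance counters (used by the simulator's own oracle tests).
evolve_branch <- function(cds, t, omega, mu = 1) {
  if (omega < 0) stopf("omega must be > 0 (0 allowed as a limit)")
  if (t < 0) stopf("branch length must be >= 0")
  gc <- genetic_code()
  x <- strsplit(cds, "")[[1]]
  L <- length(x)
  n_events <- rpois(1, mu * t * L)
  counters <- c(prop_syn = 0, prop_nonsyn = 0, acc_syn = 0, acc_nonsyn = 0,
                prop_stop = 0)
  if (n_events > 0) {
    for (e in seq_len(n_events)) {
      site <- sample.int(L, 1)
      new_base <- sample(setdiff(BASES, x[site]), 1)
      cstart <- site - (site - 1) %% 3
      old_codon <- paste(x[cstart:(cstart + 2)], collapse = "")
      new_codon <- old_codon
      substr(new_codon, site - cstart + 1, site - cstart + 1) <- new_base
      if (gc[[new_codon]] == "*") {
        counters["prop_stop"] <- counters["prop_stop"] + 1
        next
      }
      syn <- gc[[new_codon]] == gc[[old_codon]]
      if (syn) {
        counters["prop_syn"] <- counters["prop_syn"] + 1
        accept <- if (omega <= 1) TRUE else runif(1) < 1 / omega
        if (accept) counters["acc_syn"] <- counters["acc_syn"] + 1
      } else {
        counters["prop_nonsyn"] <- counters["prop_nonsyn"] + 1
        accept <- if (omega <= 1) runif(1) < omega else TRUE
        if (accept) counters["acc_nonsyn"] <- counters["acc_nonsyn"] + 1
      }
      if (accept) x[site] <- new_base
    }
  }
  list(cds = paste(x, collapse = ""), counters = counters)
}

#' Simulate one ortholog triplet on the fixed three-taxon topology
#'
#' The ancestral CDS evolves along the internal branch to the ancestor of
#' the sister pair (A, B), then independently to A and to B, and along a
#' separate branch from the root to the outgroup C.
#'
#' @param ancestral_cds Valid CDS (no stops).
#' @param tree Named numeric vector of branch lengths
#'   `c(internal =, A =, B =, C =)`, in expected synonymous substitutions
#'   per synonymous site.
#' @param omega dN/dS for the gene (> 0; 0 allowed as a purifying limit).
#' @param mu Proposal events per nucleotide site per unit branch length.
#' @param seed Optional seed; if given the draw is deterministic.
#' @return List with per-species CDS (`A`, `B`, `C`) and summed proposal /
#'   acceptance `counters`.
#' @export
simulate_codon_triplet <- function(ancestral_cds, tree, omega, mu = 1,
                                   seed = NULL) {
  stopifnot(all(c("internal", "A", "B", "C") %in% names(tree)))
  if (omega < 0) stopf("omega must be positive (0 allowed as a limit)")
  run <- function() {
    anc_ab <- evolve_branch(ancestral_cds, tree[["internal"]], omega, mu)
    a <- evolve_branch(anc_ab$cds, tree[["A"]], omega, mu)
    b <- evolve_branch(anc_ab$cds, tree[["B"]], omega, mu)
    c_ <- evolve_branch(ancestral_cds, tree[["C"]], omega, mu)
    list(A = a$cds, B = b$cds, C = c_$cds,
         counters = anc_ab$counters + a$counters + b$counters + c_$counters)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default simulation parameters
#'
#' Study conditions for the sequence stage of a recently diverged fish
#' trio (sisters split about 2 Ma, root about 5 Ma): genes of 100-300
#' codons; branch lengths giving pairwise synonymous divergence of about
#' 0.04 between the sister species and 0.10 to the outgroup; a gene pool
#' dominated by purifying selection with a small positively selected
#' fraction (a few percent of genes with omega > 1); and a 5%
#' paralog-contaminant class whose extra synonymous divergence (0.4) is at
#' least three times the tree depth.
#'
#' @param n_genes Number of ortholog triplets.
#' @param seed RNG seed (fully determines the output).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 150, seed = 1) {
  structure(list(
    n_genes = n_genes,
    codons_per_gene = c(100L, 300L),
    tree = c(internal = 0.03, A = 0.02, B = 0.02, C = 0.05),
    omega_fractions = c(purifying = 0.85, neutral = 0.10, positive = 0.05),
    omega_ranges = list(purifying = c(0.05, 0.4), neutral = c(0.9, 1.1),
                        positive = c(1.2, 2.5)),
    mu = 1,
    paralog_rate = 0.05,
    paralog_extra_ds = 0.4,
    seed = seed), class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_genes < 1) stopf("n_genes must be >= 1")
  if (p$paralog_rate < 0 || p$paralog_rate > 1)
    stopf("paralog_rate must be in [0, 1]")
  if (p$paralog_extra_ds < 0) stopf("paralog_extra_ds must be >= 0")
  if (any(p$tree < 0)) stopf("branch lengths must be >= 0")
  if (abs(sum(p$omega_fractions) - 1) > 1e-8)
    stopf("omega_fractions must sum to 1")
  invisible(p)
}

#' Simulate a full three-species ortholog dataset with known truth
#'
#' Emits one CDS per gene per species. For a `paralog_rate` fraction of
#' genes, one randomly chosen species' copy is replaced by a duplicate
#' evolved for `paralog_extra_ds` additional synonymous branch length,
#' emulating the high-dS false-positive class that contaminates
#' reciprocal-best-hit ortholog calls.
#'
#' @param params A [sim_params()] list. `omega_per_gene` may be supplied as
#'   an extra element to fix per-gene truth instead of sampling.
#' @return List with `fasta` (named list HCAR/HMAC/HFLA of named CDS
#'   vectors) and `truth` (`data.frame`: gene, per-species ids, true omega,
#'   omega class, `is_paralog`, contaminated species).
#' @export
simulate_dataset <- function(params = sim_params()) {
  validate_sim_params(params)
  with_seed(params$seed, {
    n <- params$n_genes
    classes <- sample(names(params$omega_fractions), n, replace = TRUE,
                      prob = params$omega_fractions)
    omega <- if (!is.null(params$omega_per_gene)) {
      stopifnot(length(params$omega_per_gene) == n)
      params$omega_per_gene
    } else {
      vapply(classes, function(cl)
        runif(1, params$omega_ranges[[cl]][1], params$omega_ranges[[cl]][2]),
        numeric(1))
    }
    lens <- if (length(params$codons_per_gene) == 2)
      sample(params$codons_per_gene[1]:params$codons_per_gene[2], n,
             replace = TRUE)
    else rep_len(params$codons_per_gene, n)
    is_paralog <- runif(n) < params$paralog_rate
    # map species slots: A = HCAR, B = HMAC (sisters), C = HFLA (outgroup)
    slot2sp <- c(A = "HCAR", B = "HMAC", C = "HFLA")
    seqs <- list(HCAR = character(n), HMAC = character(n), HFLA = character(n))
    contam_sp <- rep(NA_character_, n)
    for (g in seq_len(n)) {
      anc <- random_cds(lens[g])
      trip <- simulate_codon_triplet(anc, params$tree, omega[g], params$mu)
      copies <- c(HCAR = trip$A, HMAC = trip$B, HFLA = trip$C)
      if (is_paralog[g]) {
        sp <- sample(names(copies), 1)
        dup <- evolve_branch(copies[[sp]], params$paralog_extra_ds,
                             omega[g], params$mu)
        copies[[sp]] <- dup$cds
        contam_sp[g] <- sp
      }
      for (sp in names(copies)) seqs[[sp]][g] <- copies[[sp]]
    }
    base_ids <- sprintf("g%04d", seq_len(n))
    fasta <- lapply(names(seqs), function(sp)
      setNames(seqs[[sp]], paste0(sp, "_", base_ids)))
    names(fasta) <- names(seqs)
    truth <- data.frame(
      gene = base_ids,
      HCAR = paste0("HCAR_", base_ids),
      HMAC = paste0("HMAC_", base_ids),
      HFLA = paste0("HFLA_", base_ids),
      omega = omega, omega_class = classes,
      n_codons = lens,
      is_paralog = is_paralog, contaminated_species = contam_sp,
      stringsAsFactors = FALSE)
    list(fasta = fasta, truth = truth, params = params)
  })
}

#' Simulate GO annotations with planted enrichment effects
#'
#' Terms draw their member genes uniformly; planted terms record an effect
#' size in the truth table, and the caller shifts the continuous per-gene
#' measure of member genes by that effect (the enrichment stage is tested
#' against this construction).
#'
#' @param gene_ids Character vector of annotated genes.
#' @param n_terms Terms per domain-agnostic pool (domains assigned round
#'   robin across BP/CC/MF).
#' @param genes_per_term Members drawn per term (must be <= length(gene_ids)).
#' @param planted Named numeric vector: term index ("T01"...) -> effect to
#'   add to member genes' measure. Defaults to none.
#' @param seed RNG seed.
#' @return List: `annotation` (long `data.frame` gene_id/term/domain),
#'   `truth` (`data.frame` term/domain/effect/members as list column).
#' @export
simulate_go <- function(gene_ids, n_terms = 30, genes_per_term = 20,
                        planted = numeric(0), seed = 1) {
  if (genes_per_term > length(gene_ids))
    stopf("genes_per_term (%d) exceeds number of genes (%d)",
          genes_per_term, length(gene_ids))
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    domains <- rep(c("BP", "CC", "MF"), length.out = n_terms)
    members <- lapply(seq_len(n_terms), function(i)
      sample(gene_ids, genes_per_term))
    effect <- rep(0, n_terms)
    if (length(planted) > 0) {
      idx <- match(names(planted), sprintf("T%02d", seq_len(n_terms)))
      if (anyNA(idx)) stopf("planted term label not among T01..T%02d", n_terms)
      effect[idx] <- planted
    }
    annotation <- data.frame(
      gene_id = unlist(members),
      term = rep(terms, each = genes_per_term),
      domain = rep(domains, each = genes_per_term),
      stringsAsFactors = FALSE)
    truth <- data.frame(term = terms, domain = domains, effect = effect,
                        stringsAsFactors = FALSE)
    truth$members <- members
    list(annotation = annotation, truth = truth)
  })
}

#' Apply planted GO effects to a per-gene measure
#'
#' @param measure Named numeric vector (gene-level measure).
#' @param go_truth Truth table from [simulate_go()].
#' @return Shifted measure.
#' @export
apply_planted_effects <- function(measure, go_truth) {
  for (i in seq_len(nrow(go_truth))) {
    eff <- go_truth$effect[i]
    if (eff == 0) next
    m <- intersect(go_truth$members[[i]], names(measure))
    measure[m] <- measure[m] + eff
  }
  measure
}

#' Simulate a negative-binomial counts matrix for the three species
#'
#' Counts are NB with mean = size factor x baseline x 2^(species log2 fold
#' change) and gene-wise dispersion. With `outlier_subgroup = TRUE`, half of
#' the HFLA samples carry a small reproductive-marker gene set (emulating
#' vitellogenin-like upregulation) with a large extra fold change.
#'
#' @param n_genes Number of genes.
#' @param samples_per_species Named integer vector; defaults to an
#'   unbalanced 8 HCAR, 17 HFLA, 11 HMAC design typical of wild sampling.
#' @param size_factor_range Per-sample depth multipliers drawn uniformly.
#' @param dispersion Mean NB dispersion (gene-wise values drawn around it).
#' @param de_fraction Fraction of genes with true species effects.
#' @param lfc_scale SD of per-species log2 fold changes for DE genes.
#' @param outlier_subgroup Add the marker outlier subgroup?
#' @param n_markers Marker genes in the outlier set.
#' @param marker_lfc Extra log2 fold change of markers in outlier samples.
#' @param seed RNG seed.
#' @return List: `counts` (integer matrix), `meta` (sample metadata),
#'   `truth` (per-gene `data.frame` with per-species true lfc, `null`,
#'   `is_marker`, dispersion) and `outlier_samples`.
#' @export
simulate_counts <- function(n_genes = 2000,
                            samples_per_species = c(HCAR = 8, HFLA = 17,
                                                    HMAC = 11),
                            size_factor_range = c(0.7, 1.4),
                            dispersion = 0.2,
                            de_fraction = 0.1,
                            lfc_scale = 1,
                            outlier_subgroup = FALSE,
                            n_markers = 10,
                            marker_lfc = 6,
                            seed = 1) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction in [0,1]")
  with_seed(seed, {
    species <- rep(names(samples_per_species), samples_per_species)
    sample_ids <- unlist(lapply(names(samples_per_species), function(sp)
      paste0(sp, "_s", seq_len(samples_per_species[[sp]]))))
    n_samp <- length(sample_ids)
    sf <- runif(n_samp, size_factor_range[1], size_factor_range[2])
    baseline <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    disp <- pmax(dispersion * rlnorm(n_genes, 0, 0.3), 1e-4)
    is_de <- runif(n_genes) < de_fraction
    lfc <- matrix(0, n_genes, length(samples_per_species),
                  dimnames = list(NULL, names(samples_per_species)))
    lfc[is_de, ] <- rnorm(sum(is_de) * ncol(lfc), 0, lfc_scale)
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    is_marker <- rep(FALSE, n_genes)
    outlier_samples <- character(0)
    if (outlier_subgroup) {
      is_marker[seq_len(min(n_markers, n_genes))] <- TRUE
      hfla <- sample_ids[species == "HFLA"]
      outlier_samples <- hfla[seq_len(floor(length(hfla) / 2))]
    }
    mu <- baseline * 2^lfc[, match(species, colnames(lfc))]
    mu <- sweep(mu, 2, sf, `*`)
    if (outlier_subgroup) {
      out_idx <- match(outlier_samples, sample_ids)
      mu[is_marker, out_idx] <- mu[is_marker, out_idx] * 2^marker_lfc
    }
    counts <- matrix(rnbinom(n_genes * n_samp, mu = mu,
                             size = 1 / rep(disp, n_samp)),
                     n_genes, n_samp,
                     dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"
    truth <- data.frame(gene_id = gene_ids, baseline = baseline,
                        dispersion = disp, null = !is_de,
                        is_marker = is_marker, stringsAsFactors = FALSE)
    truth <- cbind(truth, setNames(as.data.frame(lfc),
                                   paste0("lfc_", colnames(lfc))))
    meta <- data.frame(sample_id = sample_ids, species = species,
                       exclude = FALSE, stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, truth = truth,
         outlier_samples = outlier_samples)
  })
}

#' Write a simulated dataset to disk
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$fasta))
    write_fasta(sim$fasta[[sp]], file.path(outdir, paste0(sp, "_cds.fasta")))
  tr <- sim$truth
  tr$contaminated_species[is.na(tr$contaminated_species)] <- ""
  write.table(tr, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
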