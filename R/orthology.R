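# Candidate ortholog calling: three-way reciprocal best hits under explicit
# acceptance thresholds (e-value < 1e-5, identity > 75%, alignment covering
# > 50% of the subject protein), an independent Markov-clustering orthology
# on the -log10(e-value) similarity graph, and the final concordance
# intersection in which only groups called by every method are retained.

#' Acceptance rule for a similarity hit
#'
#' A hit supports orthology iff e-value < 1e-5, percent identity > 75 and
#' alignment length > 50% of the subject sequence length (all strict).
#'
#' @param hit One-row hit `data.frame` (or vectorised rows).
#' @param subject_len Full subject protein length(s), residues.
#' @param max_evalue,min_identity,min_coverage The three thresholds.
#' @return Logical vector.
#' @export
accept_hit <- function(hit, subject_len, max_evalue = 1e-5,
                       min_identity = 75, min_coverage = 0.5) {
  if (any(subject_len <= 0)) stopf("subject_len must be positive")
  hit$evalue < max_evalue &
    hit$pct_identity > min_identity &
    hit$aln_length > min_coverage * subject_len
}

# Best accepted hit per query: max bitscore, ties by lower e-value, then
# lexicographic subject id. Returns named character vector query -> subject.
best_hits <- function(hits, subject_lens, ...) {
  if (nrow(hits) == 0) return(character(0))
  ok <- accept_hit(hits, subject_lens[hits$subject_id], ...)
  h <- hits[ok & !is.na(ok), ]
  if (nrow(h) == 0) return(character(0))
  h <- h[order(h$query_id, -h$bitscore, h$evalue, h$subject_id), ]
  h <- h[!duplicated(h$query_id), ]
  setNames(h$subject_id, h$query_id)
}

# Reciprocal best pairs between two species from the two ordered hit
# tables. Returns data.frame(x, y): x's best hit is y and vice versa.
rbb_pairs <- function(hits_xy, hits_yx, lens_x, lens_y, ...) {
  bx <- best_hits(hits_xy, lens_y, ...)
  by <- best_hits(hits_yx, lens_x, ...)
  x <- names(bx)
  keep <- !is.na(by[bx[x]]) & by[bx[x]] == x
  data.frame(x = x[keep], y = unname(bx[x[keep]]), stringsAsFactors = FALSE)
}

#' Three-way reciprocal-best-hit ortholog candidates
#'
#' A triplet is emitted iff the reference-species gene is a reciprocal best
#' hit with one gene in each other species and those two genes are
#' reciprocal best hits with each other (the strictest reading: all three
#' pairwise RBBs must hold).
#'
#' @param hits Named list of the six ordered hit tables, names like
#'   `"HCAR_HMAC"` (query species, subject species).
#' @param protein_lens Named list per species of protein lengths (residues),
#'   named by gene id.
#' @param reference Reference species (default `"HMAC"`).
#' @param ... Threshold overrides passed to [accept_hit()].
#' @return `data.frame` with one gene column per species plus `ref_gene`.
#' @export
reciprocal_best_triplets <- function(hits, protein_lens,
                                     reference = "HMAC", ...) {
  species <- names(protein_lens)
  if (length(species) != 3) stopf("need exactly 3 species")
  if (!reference %in% species) stopf("unknown reference '%s'", reference)
  others <- setdiff(species, reference)
  need <- as.vector(outer(species, species, function(a, b) paste0(a, "_", b)))
  need <- need[!need %in% paste0(species, "_", species)]
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0) stopf("missing hit table(s): %s",
                                 paste(missing, collapse = ", "))
  pair <- function(a, b) rbb_pairs(hits[[paste0(a, "_", b)]],
                                   hits[[paste0(b, "_", a)]],
                                   protein_lens[[a]], protein_lens[[b]], ...)
  r1 <- pair(reference, others[1])          # ref -> other1
  r2 <- pair(reference, others[2])          # ref -> other2
  r3 <- pair(others[1], others[2])          # other1 -> other2
  m1 <- setNames(r1$y, r1$x)
  m2 <- setNames(r2$y, r2$x)
  m3 <- setNames(r3$y, r3$x)
  ref_genes <- intersect(names(m1), names(m2))
  keep <- ref_genes[!is.na(m3[m1[ref_genes]]) &
                      m3[m1[ref_genes]] == m2[ref_genes]]
  out <- data.frame(ref_gene = keep, stringsAsFactors = FALSE)
  out[[reference]] <- keep
  out[[others[1]]] <- unname(m1[keep])
  out[[others[2]]] <- unname(m2[keep])
  rownames(out) <- NULL
  out[, c(SPECIES3[SPECIES3 %in% species], "ref_gene")]
}

#' Similarity graph for Markov clustering
#'
#' Symmetric adjacency over all genes of the three species; the weight of an
#' edge is the maximum `-log10(e-value)` over hits between the pair, capped
#' at 200. Self-loops are added with weight equal to the node's maximum
#' incident weight (standard MCL practice; isolated nodes get weight 1).
#'
#' @param hits Named list of ordered hit tables (as in
#'   [reciprocal_best_triplets()]).
#' @param genes Character vector of all gene ids (graph nodes).
#' @return Dense symmetric adjacency matrix.
#' @export
build_similarity_graph <- function(hits, genes) {
  n <- length(genes)
  adj <- matrix(0, n, n, dimnames = list(genes, genes))
  for (h in hits) {
    if (nrow(h) == 0) next
    w <- pmin(-log10(pmax(h$evalue, 1e-200)), 200)
    i <- match(h$query_id, genes)
    j <- match(h$subject_id, genes)
    ok <- !is.na(i) & !is.na(j)
    for (k in which(ok)) {
      if (w[k] > adj[i[k], j[k]]) {
        adj[i[k], j[k]] <- w[k]
        adj[j[k], i[k]] <- w[k]
      }
    }
  }
  diag(adj) <- 0
  loop <- apply(adj, 1, max)
  loop[loop == 0] <- 1
  diag(adj) <- loop
  adj
}

#' Markov clustering of a weighted similarity graph
#'
#' The column-stochastic matrix is iterated by expansion (matrix square) and
#' inflation (entrywise power then column renormalisation) until the largest
#' entry change falls below 1e-6 or 100 iterations; clusters are the
#' connected components of the converged attractor structure. Deterministic.
#'
#' @param adj Symmetric nonnegative adjacency matrix with dimnames.
#' @param inflation Inflation exponent (> 1; default 1.5, the default of the
#'   OrthoMCL-family tools this stage emulates).
#' @param tol Convergence threshold on the max entry change.
#' @param max_iter Iteration cap (on hitting it the current clustering is
#'   returned with a warning).
#' @return Named integer vector: gene -> cluster id.
#' @export
mcl_cluster <- function(adj, inflation = 1.5, tol = 1e-6, max_iter = 100) {
  if (inflation <= 1) stopf("inflation must be > 1")
  if (any(adj < 0)) stopf("edge weights must be >= 0")
  stopifnot(!is.null(rownames(adj)))
  M <- adj
  if (any(diag(M) == 0)) diag(M)[diag(M) == 0] <- 1
  normalise <- function(X) sweep(X, 2, colSums(X), `/`)
  M <- normalise(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- normalise(M2^inflation)      # inflation
    M2[M2 < 1e-12] <- 0                # prune for stability
    M2 <- normalise(M2)
    cs <- colSums(M2)
    if (any(abs(cs - 1) > 1e-9)) stopf("MCL column sums drifted from 1")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge in %d iterations; clustering the current matrix",
          max_iter)
  keep <- M > 1e-5
  g <- igraph::graph_from_adjacency_matrix(keep | t(keep), mode = "undirected")
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), rownames(adj))
}

#' Concordance intersection of the orthology calls
#'
#' A candidate triplet is retained iff it passed the reciprocal-best-hit
#' stage, was kept by the dS false-positive filter, and its three members
#' co-occur in a single Markov cluster.
#'
#' @param candidates Candidate triplets from [reciprocal_best_triplets()].
#' @param ds_keep Logical vector (one per candidate) from
#'   [ds_false_positive_filter()].
#' @param clusters Named membership vector from [mcl_cluster()].
#' @return List: `groups` (candidates plus `passed_rbb`, `passed_ds_filter`,
#'   `in_mcl_cluster`, `retained`), `retention_fraction`.
#' @export
concordance_filter <- function(candidates, ds_keep, clusters) {
  stopifnot(nrow(candidates) == length(ds_keep))
  sp_cols <- intersect(SPECIES3, names(candidates))
  in_cluster <- vapply(seq_len(nrow(candidates)), function(i) {
    members <- unlist(candidates[i, sp_cols], use.names = FALSE)
    ids <- clusters[members]
    !anyNA(ids) && length(unique(ids)) == 1
  }, logical(1))
  groups <- candidates
  groups$passed_rbb <- TRUE
  groups$passed_ds_filter <- ds_keep
  groups$in_mcl_cluster <- in_cluster
  groups$retained <- groups$passed_rbb & ds_keep & in_cluster
  list(groups = groups,
       retention_fraction = mean(groups$retained))
}
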