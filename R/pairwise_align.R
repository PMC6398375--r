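# Protein-protein local alignment and hit statistics, so the pipeline can
# produce its own all-vs-all hit tables. E-values use fixed ungapped
# BLOSUM62 Karlin-Altschul constants (lambda = 0.267, K = 0.041) even though
# alignments are gapped: e-values here only gate and rank orthology calls,
# so rank fidelity matters more than absolute calibration.

get_blosum62 <- function() {
  if (is.null(.os_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .os_cache$blosum62 <- e$BLOSUM62
  }
  .os_cache$blosum62
}

encode_protein <- function(protein, alphabet) {
  codes <- match(strsplit(protein, "")[[1]], alphabet) - 1L
  if (anyNA(codes))
    stopf("residue outside the substitution matrix alphabet in '%s'",
          substr(protein, 1, 20))
  codes
}

#' Optimal local protein alignment with affine gaps
#'
#' Smith-Waterman over a substitution matrix, gap of length k costing
#' `gap_open + k * gap_extend`. Tie-breaking in the traceback is
#' deterministic: diagonal, then up, then left.
#'
#' @param query,subject Protein strings (standard amino-acid alphabet).
#' @param matrix Substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Affine gap penalties (conventional protein
#'   search defaults 11 and 1).
#' @return List of class `local_alignment`: `score`, 1-based inclusive
#'   `q_start`/`q_end`/`s_start`/`s_end`, `aligned_query`,
#'   `aligned_subject` (gap character `-`), `matrix`, `gap_open`,
#'   `gap_extend`. An all-negative comparison yields an empty alignment
#'   with score 0.
#' @export
smith_waterman <- function(query, subject, matrix = get_blosum62(),
                           gap_open = 11, gap_extend = 1) {
  if (nchar(query) == 0 || nchar(subject) == 0)
    stopf("empty sequence in smith_waterman")
  alphabet <- rownames(matrix)
  q <- encode_protein(query, alphabet)
  s <- encode_protein(subject, alphabet)
  res <- .sw_align(q, s, matrix, gap_open, gap_extend)
  decode_alignment(res, alphabet, gap_open, gap_extend)
}

#' Re-score an alignment from its columns
#'
#' Independent of the DP: sums substitution scores over residue columns and
#' affine penalties over gap runs. Used as an internal consistency check.
#'
#' @param aln A `local_alignment`.
#' @param matrix Substitution matrix.
#' @return Numeric score.
#' @export
rescore_alignment <- function(aln, matrix = get_blosum62()) {
  qa <- strsplit(aln$aligned_query, "")[[1]]
  sa <- strsplit(aln$aligned_subject, "")[[1]]
  stopifnot(length(qa) == length(sa))
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || sa[k] == "-") {
      score <- score - aln$gap_extend - (!in_gap) * aln$gap_open
      in_gap <- TRUE
    } else {
      score <- score + matrix[qa[k], sa[k]]
      in_gap <- FALSE
    }
  }
  score
}

#' Hit statistics for a local alignment
#'
#' Percent identity is identical columns over alignment length; the bit
#' score is `(lambda * S - ln K) / ln 2` with fixed ungapped BLOSUM62
#' constants lambda = 0.267, K = 0.041; the e-value is
#' `m * n * 2^(-bitscore)` with `m` the query length and `n` the search
#' space (subject database residues).
#'
#' @param aln A `local_alignment`.
#' @param query_id,subject_id Ids for the emitted record.
#' @param query_len Query length (residues).
#' @param db_size Total residues in the subject database.
#' @return One-row hit `data.frame` in the 12-column dialect.
#' @export
hit_stats <- function(aln, query_id, subject_id, query_len, db_size,
                      lambda = 0.267, K = 0.041) {
  qa <- strsplit(aln$aligned_query, "")[[1]]
  sa <- strsplit(aln$aligned_subject, "")[[1]]
  len <- length(qa)
  if (len == 0) stopf("empty alignment has no hit statistics")
  ident <- sum(qa == sa & qa != "-")
  gaps <- qa == "-" | sa == "-"
  gap_opens <- sum(gaps & !c(FALSE, gaps[-len]))
  bitscore <- (lambda * aln$score - log(K)) / log(2)
  evalue <- query_len * db_size * 2^(-bitscore)
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100 * ident / len, aln_length = len,
             mismatches = sum(!gaps & qa != sa), gap_opens = gap_opens,
             q_start = aln$q_start, q_end = aln$q_end,
             s_start = aln$s_start, s_end = aln$s_end,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' All-vs-all protein search between two proteomes
#'
#' For every query, reports hits with e-value below `report_threshold`,
#' sorted by bit score descending with ties broken by subject id.
#'
#' @param query_proteins,subject_proteins Named character vectors.
#' @param report_threshold E-value reporting cutoff.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Hit `data.frame` in the 12-column dialect.
#' @export
all_vs_all <- function(query_proteins, subject_proteins,
                       report_threshold = 1e-3,
                       gap_open = 11, gap_extend = 1) {
  out <- vector("list", length(query_proteins))
  db_size <- sum(nchar(subject_proteins))
  mat <- get_blosum62()
  alphabet <- rownames(mat)
  qenc <- lapply(query_proteins, encode_protein, alphabet)
  senc <- lapply(subject_proteins, encode_protein, alphabet)
  for (i in seq_along(query_proteins)) {
    rows <- list()
    for (j in seq_along(subject_proteins)) {
      res <- .sw_align(qenc[[i]], senc[[j]], mat, gap_open, gap_extend)
      if (res$score <= 0) next
      aln <- decode_alignment(res, alphabet, gap_open, gap_extend)
      h <- hit_stats(aln, names(query_proteins)[i],
                     names(subject_proteins)[j],
                     nchar(query_proteins[[i]]), db_size)
      if (h$evalue < report_threshold) rows[[length(rows) + 1]] <- h
    }
    if (length(rows) > 0) {
      d <- do.call(rbind, rows)
      out[[i]] <- d[order(-d$bitscore, d$subject_id), ]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_hits() else `rownames<-`(res, NULL)
}

decode_alignment <- function(res, alphabet, gap_open, gap_extend) {
  decode <- function(v) {
    out <- rep("-", length(v))
    out[v >= 0] <- alphabet[v[v >= 0] + 1]
    paste(out, collapse = "")
  }
  structure(list(
    score = res$score,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    aligned_query = if (length(res$q_aln)) decode(res$q_aln) else "",
    aligned_subject = if (length(res$s_aln)) decode(res$s_aln) else "",
    matrix = "BLOSUM62", gap_open = gap_open, gap_extend = gap_extend),
    class = "local_alignment")
}

# Swap query and subject roles of a local alignment (score and columns are
# symmetric; only coordinates and strings exchange).
swap_alignment <- function(aln) {
  structure(list(
    score = aln$score,
    q_start = aln$s_start, q_end = aln$s_end,
    s_start = aln$q_start, s_end = aln$q_end,
    aligned_query = aln$aligned_subject,
    aligned_subject = aln$aligned_query,
    matrix = aln$matrix, gap_open = aln$gap_open,
    gap_extend = aln$gap_extend), class = "local_alignment")
}

# Both ordered hit tables of one unordered proteome pair from a single
# alignment pass (the alignment is role-symmetric; e-values differ via the
# query length and the subject database size).
all_vs_all_both <- function(prot_a, prot_b, report_threshold = 1e-3,
                            gap_open = 11, gap_extend = 1) {
  mat <- get_blosum62()
  alphabet <- rownames(mat)
  aenc <- lapply(prot_a, encode_protein, alphabet)
  benc <- lapply(prot_b, encode_protein, alphabet)
  db_a <- sum(nchar(prot_a))
  db_b <- sum(nchar(prot_b))
  rows_ab <- list(); rows_ba <- list()
  for (i in seq_along(prot_a)) {
    for (j in seq_along(prot_b)) {
      res <- .sw_align(aenc[[i]], benc[[j]], mat, gap_open, gap_extend)
      if (res$score <= 0) next
      aln <- decode_alignment(res, alphabet, gap_open, gap_extend)
      h1 <- hit_stats(aln, names(prot_a)[i], names(prot_b)[j],
                      nchar(prot_a[[i]]), db_b)
      if (h1$evalue < report_threshold)
        rows_ab[[length(rows_ab) + 1]] <- h1
      h2 <- hit_stats(swap_alignment(aln), names(prot_b)[j],
                      names(prot_a)[i], nchar(prot_b[[j]]), db_a)
      if (h2$evalue < report_threshold)
        rows_ba[[length(rows_ba) + 1]] <- h2
    }
  }
  finish <- function(rows) {
    if (length(rows) == 0) return(empty_hits())
    d <- do.call(rbind, rows)
    d <- d[order(d$query_id, -d$bitscore, d$subject_id), ]
    `rownames<-`(d, NULL)
  }
  list(ab = finish(rows_ab), ba = finish(rows_ba))
}
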