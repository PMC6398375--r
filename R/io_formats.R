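#' Read a FASTA file with strict validation
#'
#' Reads nucleotide or protein FASTA via Biostrings, normalises case and line
#' wrapping, and maps U to T for nucleotide input. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` (A/C/G/T only after U->T mapping) or
#'   `"protein"` (the 20 standard amino acids plus `*`).
#' @return Named character vector of upper-case sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stopf("duplicate FASTA id in %s: %s", path, dup[1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (alphabet == "nucleotide") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    legal <- "^[ACGT]*$"
  } else {
    legal <- "^[ACDEFGHIKLMNPQRSTVWY*]*$"
  }
  bad <- which(!grepl(legal, seqs))
  if (length(bad) > 0) {
    i <- bad[1]
    pos <- regexpr(if (alphabet == "nucleotide") "[^ACGT]" else
      "[^ACDEFGHIKLMNPQRSTVWY*]", seqs[i])
    stopf("illegal %s character in record '%s' at position %d",
          alphabet, ids[i], as.integer(pos))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyNA(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate an in-frame CDS and validate it
#'
#' Standard genetic code; a trailing stop codon is stripped; an internal stop
#' or a length that is not a multiple of three is an error (the pipeline
#' excludes such genes with a logged reason).
#'
#' @param cds Nucleotide string (A/C/G/T).
#' @param gene_id Optional id used in error messages.
#' @return Amino-acid string.
#' @export
translate_and_validate <- function(cds, gene_id = "<cds>") {
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0)
    stopf("CDS '%s': length %d is not a positive multiple of 3", gene_id, n)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    stopf("CDS '%s': unrecognised codon '%s'", gene_id,
          codons[which(is.na(aa))[1]])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stopf("CDS '%s': internal stop codon at codon %d", gene_id,
          which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Read a 12-column tabular similarity hit file
#'
#' The conventional tab-separated hit dialect: query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end (1-based inclusive), e-value, bit score. Extra columns
#' are ignored with a warning; fewer than 12 is an error.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of typed hit records in file order.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stopf("hit file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stopf("hit file %s line %d: expected 12 tab-separated columns, got %d",
          path, which(nf < 12)[1], nf[which(nf < 12)[1]])
  if (any(nf > 12))
    warnf("hit file %s: ignoring extra columns beyond 12", path)
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x))
      stopf("hit file %s line %d: non-numeric %s '%s'",
            path, which(is.na(x))[1], what, m[which(is.na(x))[1], j])
    x
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "pct_identity"), aln_length = as.integer(num(4, "aln_length")),
    mismatches = as.integer(num(5, "mismatches")), gap_opens = as.integer(num(6, "gap_opens")),
    q_start = as.integer(num(7, "q_start")), q_end = as.integer(num(8, "q_end")),
    s_start = as.integer(num(9, "s_start")), s_end = as.integer(num(10, "s_end")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  validate_hits(hits, path)
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits, where = "<hits>") {
  if (nrow(hits) == 0) return(invisible(hits))
  if (any(hits$q_start > hits$q_end))
    stopf("%s: q_start > q_end (coordinates are 1-based inclusive)", where)
  if (any(hits$s_start > hits$s_end))
    stopf("%s: s_start > s_end (protein hits must be forward)", where)
  if (any(hits$evalue < 0)) stopf("%s: negative e-value", where)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stopf("%s: pct_identity outside [0, 100]", where)
  invisible(hits)
}

#' Write hits in the 12-column tabular dialect
#' @param hits Hit `data.frame` as from [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits[, names(empty_hits())], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene -> GO annotation table
#'
#' Format: one row per gene per domain, three tab-separated columns:
#' gene id, semicolon-separated GO ids, domain letter (BP, CC or MF).
#'
#' @param path Path to the TSV.
#' @return Long `data.frame` with columns `gene_id`, `term`, `domain`.
#' @export
read_go <- function(path) {
  if (!file.exists(path)) stopf("GO table not found: %s", path)
  raw <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    col.names = c("gene_id", "terms", "domain"),
                    quote = "", comment.char = "")
  bad_dom <- setdiff(unique(raw$domain), c("BP", "CC", "MF"))
  if (length(bad_dom) > 0)
    stopf("GO table %s: unknown domain '%s'", path, bad_dom[1])
  terms <- strsplit(raw$terms, ";", fixed = TRUE)
  out <- data.frame(
    gene_id = rep(raw$gene_id, lengths(terms)),
    term = trimws(unlist(terms)),
    domain = rep(raw$domain, lengths(terms)),
    stringsAsFactors = FALSE)
  bad <- out$term[!grepl("^GO:\\d{7}$", out$term)]
  if (length(bad) > 0)
    stopf("GO table %s: malformed term id '%s'", path, bad[1])
  unique(out)
}

#' Write a gene -> GO annotation table
#' @param go Long `data.frame` with `gene_id`, `term`, `domain`.
#' @param path Output path.
#' @export
write_go <- function(go, path) {
  stopifnot(all(c("gene_id", "term", "domain") %in% names(go)))
  key <- interaction(go$gene_id, go$domain, drop = TRUE)
  rows <- lapply(split(go, key), function(d)
    data.frame(gene_id = d$gene_id[1],
               terms = paste(sort(unique(d$term)), collapse = ";"),
               domain = d$domain[1], stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$domain), ]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample counts matrix
#'
#' First column gene ids, header row of sample ids, integer counts.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, genes in rows.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  row.names = 1, quote = "", comment.char = "")
  m <- as.matrix(d)
  if (anyDuplicated(rownames(m))) stopf("counts %s: duplicate gene ids", path)
  if (any(m < 0) || any(m != round(m)))
    stopf("counts %s: counts must be nonnegative integers", path)
  storage.mode(m) <- "integer"
  m
}

#' Write a counts matrix
#' @param counts Integer matrix, genes in rows.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `species`, optional logical `exclude`.
#'
#' @param path Path to the TSV (with header).
#' @return `data.frame` with `sample_id`, `species`, `exclude`.
#' @export
read_sample_meta <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                  quote = "", comment.char = "")
  if (!all(c("sample_id", "species") %in% names(d)))
    stopf("sample metadata %s: need columns sample_id, species", path)
  if (anyDuplicated(d$sample_id)) stopf("duplicate sample_id in %s", path)
  d$exclude <- if ("exclude" %in% names(d)) as.logical(d$exclude) else FALSE
  d[, c("sample_id", "species", "exclude")]
}

#' Write a sample metadata table
#' @param meta `data.frame` with `sample_id`, `species`, optional `exclude`.
#' @param path Output path.
#' @export
write_sample_meta <- function(meta, path) {
  if (is.null(meta$exclude)) meta$exclude <- FALSE
  write.table(meta[, c("sample_id", "species", "exclude")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
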