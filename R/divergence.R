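# Nei-Gojobori (1986) pairwise dN/dS with equal pathway weighting and
# Jukes-Cantor multiple-hit correction. Unweighted counting: no
# transition/transversion bias, mutants that create stop codons count as
# nonsynonymous when sites are classified, and multi-step pathways through
# stop codons are excluded entirely.

BASES <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_stop <- function(codon) unname(genetic_code()[codon] == "*")

#' NG86 site counts for one codon
#'
#' Each of the nine single-nucleotide mutants of the codon is classified as
#' synonymous or nonsynonymous (mutants that are stop codons count as
#' nonsynonymous). The synonymous fraction at each position, summed over the
#' three positions, gives the synonymous site count; nonsynonymous sites are
#' the complement to three.
#'
#' @param codon A sense codon string, e.g. `"TTT"`.
#' @return Named numeric vector `c(n_sites =, s_sites =)`.
#' @export
ng86_sites <- function(codon) {
  gc <- genetic_code()
  if (is.na(gc[codon])) stopf("not a codon: '%s'", codon)
  if (gc[[codon]] == "*") stopf("stop codon '%s' has no NG86 sites", codon)
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] == aa) s <- s + 1 / 3   # stop mutants are nonsynonymous
    }
  }
  c(n_sites = 3 - s, s_sites = s)
}

# Average (Nd, Sd) over all orderings of the differing positions between two
# sense codons, excluding pathways that pass through a stop codon. Returns
# c(NA, NA) if every pathway is blocked.
ng86_path_counts <- function(codon_a, codon_b) {
  gc <- genetic_code()
  diffs <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diffs)
  if (k == 0) return(c(nd = 0, sd = 0))
  perms <- if (k == 1) list(diffs) else {
    idx <- if (k == 2) list(c(1, 2), c(2, 1)) else
      list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diffs[o])
  }
  nd_tot <- 0; sd_tot <- 0; n_valid <- 0
  for (ord in perms) {
    cur <- codon_a
    nd <- 0; sd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { nd_tot <- nd_tot + nd; sd_tot <- sd_tot + sd; n_valid <- n_valid + 1 }
  }
  if (n_valid == 0) return(c(nd = NA_real_, sd = NA_real_))
  c(nd = nd_tot / n_valid, sd = sd_tot / n_valid)
}

# Cached lookup tables over the 61 sense codons: per-codon site counts and
# 61x61 pathway-averaged difference counts.
ng86_tables <- function() {
  if (!is.null(.os_cache$ng86)) return(.os_cache$ng86)
  sc <- sense_codons()
  sites <- t(vapply(sc, ng86_sites, numeric(2)))
  nd <- matrix(NA_real_, length(sc), length(sc), dimnames = list(sc, sc))
  sdm <- nd
  for (i in seq_along(sc)) {
    for (j in i:length(sc)) {
      cnt <- ng86_path_counts(sc[i], sc[j])
      nd[i, j] <- nd[j, i] <- cnt[1]
      sdm[i, j] <- sdm[j, i] <- cnt[2]
    }
  }
  .os_cache$ng86 <- list(codons = sc, sites = sites, nd = nd, sd = sdm)
  .os_cache$ng86
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stopf("CDS length %d not a multiple of 3", n)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Back-translate a protein alignment onto codons
#'
#' Maps each aligned amino-acid column to its codon column; columns with a
#' gap or ambiguity in either sequence are dropped and counted. The kept and
#' dropped codons together conserve both input CDS.
#'
#' @param cds_a,cds_b In-frame CDS whose translations the alignment covers.
#' @param protein_alignment List with `a` and `b`: equal-length aligned
#'   protein strings using `-` for gaps.
#' @return List with `codons_a`, `codons_b` (paired codon vectors),
#'   `dropped` (count of dropped alignment columns).
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment) {
  pa <- strsplit(protein_alignment$a, "")[[1]]
  pb <- strsplit(protein_alignment$b, "")[[1]]
  if (length(pa) != length(pb))
    stopf("protein alignment strings differ in length")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  ta <- strsplit(translate_and_validate(cds_a, "a"), "")[[1]]
  tb <- strsplit(translate_and_validate(cds_b, "b"), "")[[1]]
  if (paste(pa[pa != "-"], collapse = "") != paste(ta, collapse = ""))
    stopf("protein alignment does not match translation of first CDS")
  if (paste(pb[pb != "-"], collapse = "") != paste(tb, collapse = ""))
    stopf("protein alignment does not match translation of second CDS")
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-" & pa != "X" & pb != "X"
  list(codons_a = ca[ia[keep]], codons_b = cb[ib[keep]],
       dropped = sum(!keep))
}

#' NG86 pairwise divergence for paired codon columns
#'
#' Site counts are averaged over the two sequences; difference counts for
#' codon pairs differing at more than one position are averaged with equal
#' weight over all mutational pathways that avoid stop codons. Proportions
#' are corrected for multiple hits with the Jukes-Cantor formula
#' d = -3/4 log(1 - 4/3 p); p >= 3/4 marks saturation.
#'
#' @param codons_a,codons_b Equal-length character vectors of paired codons.
#' @param ids Optional pair label character vector of length 2.
#' @return List of class `pairwise_divergence`: `aligned_codons`, `N`, `S`,
#'   `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, `status` (one of `ok`,
#'   `ds_zero`, `saturated`) and `dropped_codons` (stop/ambiguous or
#'   all-pathways-blocked columns excluded from counting).
#' @export
ng86_pair <- function(codons_a, codons_b, ids = c("a", "b")) {
  if (length(codons_a) != length(codons_b))
    stopf("codon vectors differ in length")
  if (length(codons_a) == 0) stopf("no codon columns to compare")
  tab <- ng86_tables()
  ia <- match(codons_a, tab$codons)
  ib <- match(codons_b, tab$codons)
  usable <- !is.na(ia) & !is.na(ib)
  ia <- ia[usable]; ib <- ib[usable]
  nd_v <- tab$nd[cbind(ia, ib)]
  path_ok <- !is.na(nd_v)
  dropped <- sum(!usable) + sum(!path_ok)
  ia <- ia[path_ok]; ib <- ib[path_ok]
  if (length(ia) == 0) stopf("no usable codon columns between %s and %s",
                             ids[1], ids[2])
  N <- (sum(tab$sites[ia, "n_sites"]) + sum(tab$sites[ib, "n_sites"])) / 2
  S <- (sum(tab$sites[ia, "s_sites"]) + sum(tab$sites[ib, "s_sites"])) / 2
  Nd <- sum(tab$nd[cbind(ia, ib)])
  Sd <- sum(tab$sd[cbind(ia, ib)])
  pN <- Nd / N
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  dN <- jc(pN)
  dS <- jc(pS)
  status <- "ok"
  omega <- NA_real_
  if (is.na(dN) || is.na(dS)) {
    status <- "saturated"
  } else if (dS <= 0) {
    status <- "ds_zero"
  } else {
    omega <- dN / dS
  }
  structure(list(ids = ids, aligned_codons = length(ia),
                 N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, omega = omega, status = status,
                 dropped_codons = dropped),
            class = "pairwise_divergence")
}

#' Pairwise divergence straight from two CDS
#'
#' Convenience wrapper: aligns the translations (local alignment over the
#' full proteins), back-translates to codons, and runs NG86 counting.
#'
#' @param cds_a,cds_b In-frame CDS strings.
#' @param ids Pair label.
#' @return See [ng86_pair()].
#' @export
ng86_cds <- function(cds_a, cds_b, ids = c("a", "b")) {
  pa <- translate_and_validate(cds_a, ids[1])
  pb <- translate_and_validate(cds_b, ids[2])
  aln <- smith_waterman(pa, pb)
  padded <- pad_alignment(aln, pa, pb)
  cal <- codon_align(cds_a, cds_b, padded)
  ng86_pair(cal$codons_a, cal$codons_b, ids)
}

# Extend a local protein alignment to a global-style one by stacking the
# unaligned flanks as gap-opposite columns (which codon_align then drops),
# so the alignment covers both full proteins.
pad_alignment <- function(aln, query, subject) {
  lq <- substr(query, 1, aln$q_start - 1)
  ls <- substr(subject, 1, aln$s_start - 1)
  rq <- substr(query, aln$q_end + 1, nchar(query))
  rs <- substr(subject, aln$s_end + 1, nchar(subject))
  list(a = paste0(lq, strrep("-", nchar(ls)), aln$aligned_query,
                  rq, strrep("-", nchar(rs))),
       b = paste0(strrep("-", nchar(lq)), ls, aln$aligned_subject,
                  strrep("-", nchar(rq)), rs))
}

#' Read an externally computed pairwise divergence table
#'
#' Adapter for dN/dS tables produced outside the package (for example by a
#' maximum-likelihood pairwise estimator): a TSV with header and columns
#' `pair`, `gene_a`, `gene_b`, `dN`, `dS`. Omega and the status field are
#' derived here, so the downstream mixture filters and enrichment stages
#' run on external estimates unchanged.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with `pair`, `gene_a`, `gene_b`, `dN`, `dS`,
#'   `omega`, `status` (`ok` or `ds_zero`).
#' @export
read_dnds <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("pair", "gene_a", "gene_b", "dN", "dS")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stopf("divergence table %s: missing column(s) %s", path,
          paste(missing, collapse = ", "))
  if (any(d$dN < 0 | d$dS < 0, na.rm = TRUE))
    stopf("divergence table %s: negative dN or dS", path)
  d$omega <- ifelse(d$dS > 0, d$dN / d$dS, NA_real_)
  d$status <- ifelse(is.na(d$omega), "ds_zero", "ok")
  d[, c(need, "omega", "status")]
}

#' Selection-regime classification from omega
#'
#' omega < 1 purifying; omega == 1 neutral boundary; 1 < omega < 3 candidate
#' positive selection (subject to the mixture outlier filter); omega >= 3
#' excluded as unrealistically high.
#'
#' @param omega Numeric vector of defined dN/dS values.
#' @return Character vector with levels `purifying`, `neutral_boundary`,
#'   `positive_candidate`, `excluded_high`.
#' @export
classify_selection <- function(omega) {
  if (anyNA(omega)) stopf("classify_selection: omega must be defined")
  ifelse(omega < 1, "purifying",
         ifelse(omega == 1, "neutral_boundary",
                ifelse(omega < 3, "positive_candidate", "excluded_high")))
}
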