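# Literal NG86 oracles used here and by the acceptance checks: classify the
# nine single-nucleotide mutants of a codon against the code table, and
# enumerate every stop-free mutational pathway between two codons.
oracle_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    mut <- codon
    substr(mut, pos, pos) <- b
    if (gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
  }
  c(3 - s, s)
}

oracle_path_counts <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  perms <- if (length(diffs) == 1) matrix(diffs) else
    t(do.call(rbind, combinat_perms(diffs)))
  tot <- c(0, 0); nv <- 0
  for (k in seq_len(ncol(perms))) {
    cur <- a; cnt <- c(0, 0); ok <- TRUE
    for (pos in perms[, k]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) cnt[2] <- cnt[2] + 1 else cnt[1] <- cnt[1] + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + cnt; nv <- nv + 1 }
  }
  if (nv == 0) c(NA_real_, NA_real_) else tot / nv
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}
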