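# Shared fixtures built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# A tiny three-species proteome set with known one-to-one orthologs:
# identical proteins across species so every RBB is unambiguous.
tiny_proteomes <- function(n_genes = 3, len = 40, seed = 99) {
  withr::with_seed(seed, {
    base <- vapply(seq_len(n_genes), function(i) random_protein(len),
                   character(1))
    out <- lapply(c(HCAR = "HCAR", HMAC = "HMAC", HFLA = "HFLA"),
                  function(sp) setNames(base, paste0(sp, "_g", seq_len(n_genes))))
    out
  })
}

# Hand-built hit table row in the 12-column dialect.
mk_hit <- function(q, s, ident = 90, len = 100, evalue = 1e-30,
                   bitscore = 200) {
  data.frame(query_id = q, subject_id = s, pct_identity = ident,
             aln_length = len, mismatches = 0L, gap_opens = 0L,
             q_start = 1L, q_end = len, s_start = 1L, s_end = len,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}
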