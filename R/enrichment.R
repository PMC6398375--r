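# Rank-based GO enrichment: a continuous per-gene measure (dN/dS, or the
# signed log10 p-value from expression contrasts) is tested per GO term with
# a Mann-Whitney U test of members against non-members, separately for each
# domain (BP / CC / MF), with Benjamini-Hochberg FDR at 10%.

#' Signed log-p measure for expression enrichment
#'
#' `|log10 p|` signed by fold-change direction: positive for upregulated
#' genes, negative for downregulated ones. `p = 0` is clamped to the
#' smallest positive double.
#'
#' @param p_values Numeric vector in (0, 1].
#' @param directions `"up"`/`"down"`, or a numeric log fold change whose
#'   sign is used.
#' @return Numeric vector (names preserved).
#' @export
signed_logp <- function(p_values, directions) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  if (any(p_values == 0, na.rm = TRUE)) {
    warnf("p = 0 clamped to smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  sign_up <- if (is.numeric(directions)) directions >= 0
  else directions == "up"
  unlist(-log10(p_values)) * ifelse(sign_up, 1, -1)
}

# Exact two-group rank-sum distribution by enumeration over all member-rank
# subsets of the observed (mid)ranks. Feasible for n_in, n_out <= 8.
mwu_exact_p <- function(ranks, n_in, u_obs,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  sets <- combn(length(ranks), n_in)
  offset <- n_in * (n_in + 1) / 2
  u_all <- colSums(matrix(ranks[sets], nrow = n_in)) - offset
  eps <- 1e-9
  p_ge <- mean(u_all >= u_obs - eps)
  p_le <- mean(u_all <= u_obs + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Mann-Whitney U test of a gene set against its complement
#'
#' U from rank sums with midrank ties. The p-value is exact (full
#' enumeration over member-rank subsets) when both groups have at most
#' `exact_max` genes, otherwise a normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param measure Numeric vector over all genes.
#' @param members Logical or index vector marking the gene set.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (members tending to larger / smaller measure).
#' @param exact_max Group-size bound for exact enumeration.
#' @return List: `U`, `p_value`, `delta_rank` (mean member rank minus mean
#'   non-member rank), `n_in`, `n_out`, `exact`.
#' @export
mwu_term_test <- function(measure, members,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 8) {
  alternative <- match.arg(alternative)
  n <- length(measure)
  inset <- rep(FALSE, n)
  inset[members] <- TRUE
  n1 <- sum(inset)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1) stopf("need 1 <= n_in < n_genes")
  r <- rank(measure)
  U <- sum(r[inset]) - n1 * (n1 + 1) / 2
  delta_rank <- mean(r[inset]) - mean(r[!inset])
  if (length(unique(measure)) == 1) {
    return(list(U = U, p_value = 1, delta_rank = 0, n_in = n1, n_out = n2,
                exact = FALSE))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- mwu_exact_p(r, n1, U, alternative)
    return(list(U = U, p_value = max(p, .Machine$double.xmin),
                delta_rank = delta_rank, n_in = n1, n_out = n2, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, delta_rank = delta_rank,
                               n_in = n1, n_out = n2, exact = FALSE))
  z_num <- switch(alternative,
                  two.sided = abs(U - mu) - 0.5,
                  greater = U - mu - 0.5,
                  less = mu - U - 0.5)
  z <- max(z_num, 0) / sqrt(sigma2)
  p <- if (alternative == "two.sided") 2 * pnorm(-z) else pnorm(-z)
  list(U = U, p_value = min(max(p, .Machine$double.xmin), 1),
       delta_rank = delta_rank, n_in = n1, n_out = n2, exact = FALSE)
}

#' Benjamini-Hochberg adjustment with a significance call
#'
#' @param p_values Numeric vector.
#' @param q FDR level (default 0.10).
#' @return List: `p_adjusted`, `significant` (`p_adjusted <= q`).
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj <= q)
}

#' Rank-based GO enrichment over a continuous measure
#'
#' Runs [mwu_term_test()] for every term of one domain with at least
#' `min_size` annotated genes present in the measure, adjusts within the
#' domain by Benjamini-Hochberg, and returns the table sorted by p-value.
#'
#' @param measure Named numeric vector: gene id -> measure (dN/dS for the
#'   selection scan, signed log-p for expression).
#' @param annotation Long annotation `data.frame` (`gene_id`, `term`,
#'   `domain`), as from [read_go()] or [simulate_go()].
#' @param domain `"BP"`, `"CC"` or `"MF"`.
#' @param fdr FDR level for the significance flag.
#' @param min_size Minimum term size (genes with a measure).
#' @param alternative Passed to [mwu_term_test()].
#' @return `data.frame`: `term`, `domain`, `n_genes_in_term`, `delta_rank`,
#'   `U`, `p_value`, `p_adjusted`, `significant`, sorted by `p_value`.
#' @export
run_enrichment <- function(measure, annotation, domain = "BP", fdr = 0.10,
                           min_size = 5, alternative = "two.sided") {
  stopifnot(domain %in% c("BP", "CC", "MF"))
  ann <- annotation[annotation$domain == domain &
                      annotation$gene_id %in% names(measure), ]
  empty <- data.frame(term = character(), domain = character(),
                      n_genes_in_term = integer(), delta_rank = numeric(),
                      U = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(empty)
  by_term <- split(ann$gene_id, ann$term)
  by_term <- by_term[lengths(by_term) >= min_size &
                       lengths(by_term) < length(measure)]
  if (length(by_term) == 0) return(empty)
  rows <- lapply(names(by_term), function(tm) {
    res <- mwu_term_test(measure, names(measure) %in% by_term[[tm]],
                         alternative = alternative)
    data.frame(term = tm, domain = domain, n_genes_in_term = res$n_in,
               delta_rank = res$delta_rank, U = res$U, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p_value, fdr)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
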