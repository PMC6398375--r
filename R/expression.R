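# Expression stage: median-of-ratios size factors, a log2 transform of
# normalized counts, negative-binomial GLM likelihood-ratio tests across the
# three species with method-of-moments dispersion shared between the null
# and full fits, pairwise contrasts, principal coordinates on Manhattan
# distances, and the marker-based screen that formalises the exclusion of
# reproductively active outlier samples.

#' Median-of-ratios size factors
#'
#' For every gene with nonzero counts in all samples, the ratio of each
#' sample's count to the gene's geometric mean is computed; a sample's
#' factor is the median of its ratios, and factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Integer matrix, genes in rows.
#' @param pseudo_reference If no gene is nonzero in every sample, setting
#'   this to `TRUE` computes gene geometric means over nonzero samples only
#'   (logged); otherwise that situation is an error.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stopf(paste("no gene has nonzero counts in every sample;",
                  "rerun with pseudo_reference = TRUE"))
    message("size_factors: using pseudo-reference over nonzero samples")
    loggeo <- apply(counts, 1, function(y)
      if (any(y > 0)) mean(log(y[y > 0])) else NA_real_)
    use <- !is.na(loggeo)
  } else {
    loggeo <- rowMeans(log(pmax(counts, 1e-300)))
    use <- all_pos
  }
  logratios <- log(counts[use, , drop = FALSE]) - loggeo[use]
  logratios[!is.finite(logratios)] <- NA
  sf <- exp(apply(logratios, 2, median, na.rm = TRUE))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Normalised log2 transform
#'
#' `log2(count / size_factor + 1)`: a simple variance-flattening stand-in
#' for spline-based variance stabilisation, adequate for distance-based
#' ordination and the marker screen.
#'
#' @param counts Integer matrix, genes in rows.
#' @param factors Size factors (default computed from `counts`).
#' @return Numeric matrix of the same shape.
#' @export
transform_counts <- function(counts, factors = size_factors(counts)) {
  log2(sweep(counts, 2, factors, `/`) + 1)
}

# Gene-wise method-of-moments NB dispersion from within-species moments of
# normalised counts: solves E[var] = mean * mean(1/sf) + a * mean^2 per
# species, pools across species weighted by df, and applies an n/(n - g)
# small-sample correction for the g estimated group means (plugging a noisy
# dispersion into the LRT is otherwise anti-conservative). Floored at 1e-8.
mom_dispersion <- function(y, species, sf) {
  q <- y / sf
  num <- 0; den <- 0; n_used <- 0; g_used <- 0
  for (sp in unique(species)) {
    i <- species == sp
    if (sum(i) < 2) next
    m <- mean(q[i])
    if (m <= 0) next
    v <- var(q[i])
    a <- (v - m * mean(1 / sf[i])) / m^2
    w <- sum(i) - 1
    num <- num + w * a
    den <- den + w
    n_used <- n_used + sum(i)
    g_used <- g_used + 1
  }
  if (den == 0) return(1e-8)
  max(num / den * n_used / (n_used - g_used), 1e-8)
}

# NB GLM LRT with fixed theta shared between the nested fits; returns the
# chi-square p-value and the deviance difference.
nb_glm_lrt <- function(y, f, sf, disp) {
  theta <- 1 / disp
  off <- log(sf)
  fit1 <- try(glm(y ~ f + offset(off),
                  family = MASS::negative.binomial(theta = theta),
                  control = glm.control(maxit = 100)), silent = TRUE)
  fit0 <- try(glm(y ~ 1 + offset(off),
                  family = MASS::negative.binomial(theta = theta),
                  control = glm.control(maxit = 100)), silent = TRUE)
  if (inherits(fit1, "try-error") || inherits(fit0, "try-error"))
    return(list(stat = NA_real_, p = 1, note = "glm_failure"))
  stat <- max(fit0$deviance - fit1$deviance, 0)
  list(stat = stat,
       p = pchisq(stat, df = nlevels(f) - 1, lower.tail = FALSE),
       note = "ok")
}

#' Negative-binomial likelihood-ratio test for species effects
#'
#' Per gene: dispersion by method of moments on normalised counts (floored
#' at 1e-8, shared between fits), full model with a per-species mean versus
#' an intercept-only null, both with log link and size-factor offsets; the
#' LRT statistic is referred to chi-square with (n_species - 1) degrees of
#' freedom. All-zero genes get p = 1 and are flagged.
#'
#' @param counts Integer matrix, genes in rows.
#' @param species Character vector, one label per sample column.
#' @param factors Size factors (default computed).
#' @return `data.frame`: `gene_id`, per-species mean normalised counts,
#'   `dispersion`, `lrt_stat`, `p_value`, `note`.
#' @export
nb_lrt <- function(counts, species, factors = size_factors(counts)) {
  stopifnot(ncol(counts) == length(species))
  tab <- table(species)
  if (length(tab) < 2 || any(tab < 2))
    stopf("need >= 2 species with >= 2 samples each")
  f <- factor(species)
  sp_names <- levels(f)
  rows <- vector("list", nrow(counts))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    q <- y / factors
    means <- vapply(sp_names, function(sp) mean(q[f == sp]), numeric(1))
    if (all(y == 0)) {
      rows[[g]] <- data.frame(gene_id = rownames(counts)[g],
                              t(means), dispersion = NA_real_,
                              lrt_stat = 0, p_value = 1, note = "all_zero",
                              stringsAsFactors = FALSE)
      next
    }
    disp <- mom_dispersion(y, species, factors)
    res <- nb_glm_lrt(y, f, factors, disp)
    rows[[g]] <- data.frame(gene_id = rownames(counts)[g], t(means),
                            dispersion = disp, lrt_stat = res$stat,
                            p_value = res$p, note = res$note,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(sp_names))] <- paste0("mean_", sp_names)
  rownames(out) <- NULL
  out
}

#' Pairwise species contrast
#'
#' Two-group NB likelihood-ratio test (one degree of freedom) for the
#' samples of two species, with `log2FC = log2((mean2 + 0.5) /
#' (mean1 + 0.5))` of size-factor-normalised species means; positive values
#' mean upregulation in `species_b`.
#'
#' @param counts Integer matrix, genes in rows (all samples).
#' @param species Per-sample labels.
#' @param species_a,species_b The two species to contrast.
#' @param factors Size factors computed on the full matrix.
#' @return `data.frame`: `gene_id`, `log2fc`, `lrt_stat`, `p_value`.
#' @export
contrast <- function(counts, species, species_a, species_b,
                     factors = size_factors(counts)) {
  sel <- species %in% c(species_a, species_b)
  if (sum(species == species_a) < 2 || sum(species == species_b) < 2)
    stopf("need >= 2 samples for each contrasted species")
  sub <- counts[, sel, drop = FALSE]
  f <- factor(species[sel], levels = c(species_a, species_b))
  sf <- factors[sel]
  rows <- vector("list", nrow(sub))
  for (g in seq_len(nrow(sub))) {
    y <- sub[g, ]
    q <- y / sf
    m1 <- mean(q[f == species_a])
    m2 <- mean(q[f == species_b])
    lfc <- log2((m2 + 0.5) / (m1 + 0.5))
    if (all(y == 0)) {
      rows[[g]] <- data.frame(gene_id = rownames(sub)[g], log2fc = 0,
                              lrt_stat = 0, p_value = 1,
                              stringsAsFactors = FALSE)
      next
    }
    disp <- mom_dispersion(y, as.character(f), sf)
    res <- nb_glm_lrt(y, f, sf, disp)
    rows[[g]] <- data.frame(gene_id = rownames(sub)[g], log2fc = lfc,
                            lrt_stat = res$stat, p_value = res$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal coordinates from Manhattan distances
#'
#' Pairwise Manhattan distances between sample columns of the transformed
#' matrix (the sum of log-fold differences across genes), followed by
#' classical scaling: double-centre -D^2/2, eigendecompose, and scale
#' eigenvectors by the square root of their eigenvalues. Only
#' positive-eigenvalue axes are retained; any negative eigenvalue mass is
#' reported.
#'
#' @param transformed Numeric matrix (genes x samples), e.g. from
#'   [transform_counts()].
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (positive ones), `pct_variance`, `negative_mass`.
#' @export
pcoa_manhattan <- function(transformed) {
  if (ncol(transformed) < 3) stopf("PCoA needs at least 3 samples")
  d <- dist(t(transformed), method = "manhattan")
  n <- ncol(transformed)
  # cmdscale warns when trailing eigenvalues are non-positive; that mass is
  # reported explicitly below
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  ev <- fit$eig
  tol <- max(abs(ev)) * 1e-8
  pos <- which(ev > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = ev[pos],
    pct_variance = 100 * ev[pos] / sum(ev[pos]),
    negative_mass = sum(abs(ev[ev < -tol]))), class = "pcoa_result")
}

#' Marker-based outlier-sample screen
#'
#' Per sample, the marker score is the mean transformed expression of the
#' marker gene set; a sample is flagged when its score exceeds its
#' species' median score by more than `threshold` (log2 units). This
#' formalises the exclusion of reproductively active individuals whose
#' vitellogenin-like genes dominate liver expression.
#'
#' @param counts Integer matrix, genes in rows.
#' @param meta Sample metadata (`sample_id`, `species`).
#' @param markers Character vector of marker gene ids (non-empty).
#' @param threshold Flagging threshold, log2 scale (default 2).
#' @param factors Size factors.
#' @return List: `flagged` (sample ids), `scores` (named vector).
#' @export
marker_outlier_screen <- function(counts, meta, markers, threshold = 2,
                                  factors = size_factors(counts)) {
  if (length(markers) == 0) stopf("marker set is empty")
  missing <- setdiff(markers, rownames(counts))
  if (length(missing) > 0)
    stopf("marker gene(s) not in counts: %s", paste(missing, collapse = ", "))
  tr <- transform_counts(counts[markers, , drop = FALSE], factors)
  score <- colMeans(tr)
  flagged <- character(0)
  for (sp in unique(meta$species)) {
    ids <- meta$sample_id[meta$species == sp]
    s <- score[ids]
    flagged <- c(flagged, ids[s - median(s) > threshold])
  }
  list(flagged = flagged, scores = score)
}
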