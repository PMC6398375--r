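# Univariate Gaussian mixtures fitted by EM with k-means++-style starts and
# BIC model selection, plus the two filtering procedures built on them: the
# three-component dS filter that removes the highest-mean component as
# false-positive ortholog calls, and the four-component filter on omega > 1
# that removes unrealistically high dN/dS before the bounded
# positive-selection call (1 < omega < 3).

VAR_FLOOR <- 1e-8

# log-density of the mixture, n x k matrix of weighted log components
mix_log_components <- function(x, w, m, v) {
  k <- length(w)
  lc <- matrix(0, length(x), k)
  for (j in seq_len(k))
    lc[, j] <- log(w[j]) + dnorm(x, m[j], sqrt(v[j]), log = TRUE)
  lc
}

log_row_sum <- function(lc) {
  mx <- apply(lc, 1, max)
  mx + log(rowSums(exp(lc - mx)))
}

# k-means++-style seeding of initial means
kmeanspp_means <- function(x, k) {
  m <- numeric(k)
  m[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(xi) min((xi - m[1:(j - 1)])^2), numeric(1))
    if (sum(d2) == 0) m[j] <- x[sample.int(length(x), 1)]
    else m[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  m
}

#' Fit a univariate Gaussian mixture by EM
#'
#' The default initialisation partitions the sorted data into k
#' equal-frequency bins and starts EM from their moments — the
#' deterministic, agglomeration-style strategy reference mixture tools use
#' for one-dimensional data. EM then converges to the natural local
#' optimum in which an isolated high cluster stays one component, which is
#' what the drop-highest-component filters require; a multi-start
#' k-means++ search (`init = "kmeanspp"`) that hunts the global maximum
#' instead is available but can tile a tight outlying cluster with several
#' components. Each run iterates until the log-likelihood gain drops below
#' `tol` or `max_iter` iterations. Components are stored sorted by mean.
#'
#' @param values Finite numeric vector, `length(values) >= k`.
#' @param k Number of components.
#' @param n_starts Number of restarts (`init = "kmeanspp"` only).
#' @param seed RNG seed; fits are deterministic given it (the quantile
#'   initialisation uses no randomness at all).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param var_floor_frac Variance regularisation: component variances are
#'   kept above this fraction of the overall data variance (and above the
#'   1e-8 numerical floor), preventing degenerate likelihood spikes.
#' @param init `"quantile"` (default) or `"kmeanspp"`.
#' @return List of class `gmm`: `k`, `weights`, `means`, `variances`,
#'   `log_likelihood`, `bic` (`-2 logL + (3k - 1) log n`), `assignments`
#'   (max-posterior component per observation), `responsibilities`, `n`.
#' @export
fit_gmm <- function(values, k, n_starts = 10, seed = 1, tol = 1e-8,
                    max_iter = 500, var_floor_frac = 0.01,
                    init = c("quantile", "kmeanspp")) {
  init <- match.arg(init)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stopf("values must be finite")
  n <- length(x)
  if (n < k) stopf("need at least k = %d observations, got %d", k, n)
  vx <- if (n > 1) var(x) else 0
  floor_v <- max(VAR_FLOOR, var_floor_frac * vx, na.rm = TRUE)
  run_em <- function(m0, v0 = NULL, w0 = NULL) {
    w <- if (is.null(w0)) rep(1 / k, k) else w0
    m <- m0
    v <- if (is.null(v0)) rep(max(vx, floor_v), k) else pmax(v0, floor_v)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lc <- mix_log_components(x, w, m, v)
      lse <- log_row_sum(lc)
      ll <- sum(lse)
      if (ll < ll_old - 1e-6)
        stopf("EM log-likelihood decreased (internal error)")
      resp <- exp(lc - lse)
      if (ll - ll_old < tol && it > 1) break
      ll_old <- ll
      nk <- colSums(resp)
      nk <- pmax(nk, 1e-12)
      w <- nk / n
      m <- colSums(resp * x) / nk
      v <- pmax(colSums(resp * (outer(x, m, `-`))^2) / nk, floor_v)
    }
    list(w = w, m = m, v = v, ll = ll, resp = resp)
  }
  best <- if (init == "quantile") {
    bins <- if (k == 1) list(x) else
      split(sort(x), cut(seq_len(n), k, labels = FALSE))
    m0 <- vapply(bins, mean, numeric(1))
    v0 <- vapply(bins, function(b) if (length(b) > 1) var(b) else floor_v,
                 numeric(1))
    v0[!is.finite(v0)] <- floor_v
    run_em(m0, v0, lengths(bins) / n)
  } else {
    with_seed(seed, {
      fits <- lapply(seq_len(n_starts),
                     function(s) run_em(kmeanspp_means(x, k)))
      fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
    })
  }
  ord <- order(best$m)
  resp <- best$resp[, ord, drop = FALSE]
  structure(list(
    k = k,
    weights = best$w[ord],
    means = best$m[ord],
    variances = best$v[ord],
    log_likelihood = best$ll,
    bic = -2 * best$ll + (3 * k - 1) * log(n),
    assignments = max.col(resp, ties.method = "first"),
    responsibilities = resp,
    n = n), class = "gmm")
}

#' Select the mixture order by BIC
#'
#' Fits every k in `k_range` and returns the minimum-BIC model; ties go to
#' the smaller k.
#'
#' @param values Numeric vector.
#' @param k_range Candidate component counts.
#' @param ... Passed to [fit_gmm()].
#' @return The selected `gmm`, with attribute `bic_by_k`.
#' @export
select_k_bic <- function(values, k_range = 1:5, ...) {
  k_range <- sort(unique(k_range))
  k_range <- k_range[k_range <= length(values)]
  if (length(k_range) == 0) stopf("no feasible k in range")
  fits <- lapply(k_range, function(k) fit_gmm(values, k, ...))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]   # which.min returns first (smallest k) tie
  attr(best, "bic_by_k") <- setNames(bics, k_range)
  best
}

#' dS false-positive filter for candidate ortholog groups
#'
#' Pools one summary dS value per candidate group (the mean of its three
#' pairwise dS values), fits a three-component Gaussian mixture, and drops
#' every group whose max-posterior assignment is the highest-mean component
#' — the class of inflated synonymous divergence that marks paralogous
#' (false-positive) ortholog calls.
#'
#' @param ds_values Numeric vector, one summary dS per candidate group.
#' @param k Component count (3, per the filtering procedure).
#' @param ... Passed to [fit_gmm()].
#' @return List: `keep` logical vector, `model` (`gmm`), `dropped_fraction`.
#' @export
ds_false_positive_filter <- function(ds_values, k = 3, ...) {
  if (length(unique(ds_values)) < k)
    stopf("need at least %d distinct dS values, got %d", k,
          length(unique(ds_values)))
  model <- fit_gmm(ds_values, k, ...)
  keep <- model$assignments != model$k
  list(keep = keep, model = model, dropped_fraction = mean(!keep))
}

#' High-omega outlier filter and bounded positive-selection call
#'
#' For one pairwise species comparison: fits a four-component Gaussian
#' mixture to the dN/dS values above 1, removes members of the highest-mean
#' component as unrealistic, and flags the remaining genes with
#' 1 < omega < 3 as positively selected. With fewer than `min_n`
#' observations above 1 the mixture is skipped and a hard omega < 3 cut is
#' applied (with a warning).
#'
#' @param omega Named numeric vector of defined dN/dS values (all genes of
#'   one comparison; only those > 1 enter the mixture).
#' @param k Component count (4, per the filtering procedure).
#' @param min_n Minimum number of omega > 1 values for a mixture fit.
#' @param ... Passed to [fit_gmm()].
#' @return List: `keep` (logical over the omega > 1 subset, named),
#'   `positive` (gene ids flagged positively selected: kept and
#'   1 < omega < 3), `model` (`gmm` or NULL), `boundary` (midpoint between
#'   the largest kept and smallest dropped omega; NA without a mixture fit).
#' @export
omega_outlier_filter <- function(omega, k = 4, min_n = 4, ...) {
  if (is.null(names(omega))) names(omega) <- as.character(seq_along(omega))
  hi <- omega[omega > 1]
  if (length(hi) < max(k, min_n) || length(unique(hi)) < k) {
    warnf("only %d omega > 1 values: skipping the mixture, using a hard omega < 3 cut",
          length(hi))
    keep <- hi < 3
    return(list(keep = keep,
                positive = names(hi)[keep],
                model = NULL, boundary = NA_real_))
  }
  model <- fit_gmm(hi, k, ...)
  keep <- setNames(model$assignments != model$k, names(hi))
  kept_max <- suppressWarnings(max(hi[keep]))
  drop_min <- suppressWarnings(min(hi[!keep]))
  boundary <- if (is.finite(kept_max) && is.finite(drop_min))
    (kept_max + drop_min) / 2 else NA_real_
  positive <- names(hi)[keep & hi > 1 & hi < 3]
  list(keep = keep, positive = positive, model = model, boundary = boundary)
}
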