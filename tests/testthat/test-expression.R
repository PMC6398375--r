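test_that("size factors follow median-of-ratios with geometric-mean centring", {
  counts <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(A = c(5L, 8L), B = c(5L, 8L), C = c(5L, 8L))
  rownames(same) <- c("g1", "g2")
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # permutation equivariance
  withr::local_seed(61)
  m <- matrix(rpois(60, 50), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  storage.mode(m) <- "integer"
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(size_factors(m[, perm]), size_factors(m)[perm])

  # all-zero-containing genes only: error then pseudo-reference fallback
  z <- matrix(c(0L, 5L, 7L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(size_factors(z), "pseudo_reference")
  expect_message(sfz <- size_factors(z, pseudo_reference = TRUE),
                 "pseudo-reference")
  expect_equal(length(sfz), 2)
})

test_that("log2 transform maps zero to zero and is depth-invariant", {
  counts <- matrix(c(0L, 4L, 8L, 16L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("A", "B")))
  tr <- transform_counts(counts, factors = c(A = 1, B = 1))
  expect_equal(tr["g1", "A"], 0)
  expect_equal(tr["g2", "B"], log2(17))
  tr2 <- transform_counts(counts * 2L, factors = c(A = 2, B = 2))
  expect_equal(tr2, tr, ignore_attr = TRUE)
})

test_that("NB LRT detects large shifts and dies under label permutation", {
  withr::local_seed(62)
  n_per <- 6
  species <- rep(c("S1", "S2", "S3"), each = n_per)
  sf <- rep(1, 18)
  hits <- 0
  for (rep in 1:20) {
    mu <- rep(c(100, 800, 100), each = n_per)  # 8-fold shift in S2
    y <- rnbinom(18, mu = mu, size = 1 / 0.15)
    counts <- matrix(as.integer(y), 1, dimnames = list("g", NULL))
    colnames(counts) <- paste0("s", 1:18)
    p <- nb_lrt(counts, species, setNames(sf, colnames(counts)))$p_value
    if (p < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% power

  # permuting labels destroys the signal
  ps <- replicate(20, {
    mu <- rep(c(100, 800, 100), each = n_per)
    y <- rnbinom(18, mu = mu, size = 1 / 0.15)
    counts <- matrix(as.integer(y), 1, dimnames = list("g", paste0("s", 1:18)))
    nb_lrt(counts, sample(species), setNames(sf, colnames(counts)))$p_value
  })
  expect_gt(median(ps), 0.3)

  expect_error(nb_lrt(matrix(1L, 1, 3), c("a", "a", "b")), ">= 2 samples")
})

test_that("all-zero genes get p = 1 and a flag", {
  counts <- rbind(g1 = rep(0L, 12), g2 = rep(c(3L, 9L), 6))
  colnames(counts) <- paste0("s", 1:12)
  species <- rep(c("A", "B"), each = 6)
  de <- nb_lrt(counts, species, setNames(rep(1, 12), colnames(counts)))
  expect_equal(de$p_value[1], 1)
  expect_identical(de$note[1], "all_zero")
})

test_that("contrasts are antisymmetric and recover known fold changes", {
  withr::local_seed(63)
  n <- 30
  speciesv <- rep(c("A", "B"), each = n)
  mu <- c(rep(200, n), rep(800, n))  # 4-fold
  counts <- matrix(as.integer(rnbinom(2 * n * 50, mu = rep(mu, each = 50),
                                      size = 1 / 0.05)),
                   nrow = 50, dimnames = list(paste0("g", 1:50),
                                              paste0("s", 1:(2 * n))))
  sf <- setNames(rep(1, 2 * n), colnames(counts))
  ab <- contrast(counts, speciesv, "A", "B", sf)
  ba <- contrast(counts, speciesv, "B", "A", sf)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-9)
  expect_equal(median(ab$log2fc), 2, tolerance = 0.2)
})

test_that("a two-species LRT and the contrast give the same p-value", {
  withr::local_seed(64)
  counts <- matrix(as.integer(rnbinom(120, mu = 50, size = 5)), 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  species <- rep(c("A", "B"), each = 6)
  sf <- size_factors(counts)
  de <- nb_lrt(counts, species, sf)
  ct <- contrast(counts, species, "A", "B", sf)
  expect_equal(de$p_value, ct$p_value, tolerance = 1e-9)
})

test_that("PCoA on Manhattan distances is classical scaling", {
  # 3 collinear points: one positive eigenvalue carrying all variance
  m <- matrix(c(0, 1, 2), nrow = 1,
              dimnames = list("g1", c("s1", "s2", "s3")))
  res <- pcoa_manhattan(m)
  expect_equal(length(res$eigenvalues), 1)
  expect_equal(res$pct_variance, 100)
  d <- as.matrix(dist(t(m), "manhattan"))
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(rec, d, tolerance = 1e-9, ignore_attr = TRUE)

  # identical samples coincide
  m2 <- rbind(g1 = c(1, 1, 4), g2 = c(2, 2, 0))
  colnames(m2) <- c("s1", "s2", "s3")
  res2 <- pcoa_manhattan(m2)
  expect_equal(res2$coordinates["s1", ], res2$coordinates["s2", ],
               tolerance = 1e-9)

  expect_error(pcoa_manhattan(m[, 1:2, drop = FALSE]), "3 samples")
})

test_that("eigenvalue mass accounts for the retained dispersion", {
  withr::local_seed(65)
  m <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  res <- pcoa_manhattan(m)
  d2 <- as.matrix(dist(t(m), "manhattan"))^2
  total <- sum(d2) / (2 * ncol(m))   # trace of the double-centred matrix
  expect_equal(sum(res$eigenvalues) - res$negative_mass, total,
               tolerance = 1e-6)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))  # sorted descending
})

test_that("the marker screen flags only elevated samples", {
  withr::local_seed(66)
  counts <- matrix(as.integer(rnbinom(20 * 12, mu = 100, size = 10)), 20,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     species = rep(c("A", "B"), each = 6),
                     stringsAsFactors = FALSE)
  res <- marker_outlier_screen(counts, meta, c("g1", "g2"),
                               factors = setNames(rep(1, 12),
                                                  colnames(counts)))
  expect_length(res$flagged, 0)

  counts2 <- counts
  counts2[1:2, 1:2] <- counts2[1:2, 1:2] * 200L
  res2 <- marker_outlier_screen(counts2, meta, c("g1", "g2"),
                                factors = setNames(rep(1, 12),
                                                   colnames(counts)))
  expect_setequal(res2$flagged, c("s1", "s2"))
  expect_error(marker_outlier_screen(counts, meta, character(0)), "empty")
  expect_error(marker_outlier_screen(counts, meta, "nope"), "not in counts")
})
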