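test_that("signed log-p follows its definition", {
  expect_equal(signed_logp(0.01, "up"), 2)
  expect_equal(signed_logp(0.01, "down"), -2)
  expect_equal(signed_logp(1, "up"), 0)
  expect_equal(signed_logp(c(0.1, 0.1), c(2.5, -1)), c(1, -1))
  expect_warning(v <- signed_logp(0, "up"), "clamped")
  expect_true(is.finite(v) && v > 300)
  expect_error(signed_logp(1.5, "up"), "0, 1")
})

test_that("the worked rank example gives U = 6 and exact one-sided p = 0.1", {
  res <- mwu_term_test(c(1, 2, 3, 4, 5), c(4, 5), alternative = "greater")
  expect_equal(res$U, 6)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
})

test_that("U statistics of a set and its complement conserve n1*n2", {
  withr::local_seed(51)
  x <- rnorm(20)
  members <- sample(20, 7)
  u_in <- mwu_term_test(x, members)$U
  u_out <- mwu_term_test(x, setdiff(1:20, members))$U
  expect_equal(u_in + u_out, 7 * 13)
})

test_that("exact p-values agree with wilcox.test on tie-free data", {
  withr::local_seed(52)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    n1 <- sample(2:min(8, n - 2), 1)
    if (n - n1 > 8) n1 <- n - 8
    x <- rnorm(n)
    members <- sample(n, n1)
    for (alt in c("two.sided", "greater", "less")) {
      mine <- mwu_term_test(x, members, alternative = alt)
      ref <- wilcox.test(x[members], x[-members], alternative = alt,
                         exact = TRUE, correct = FALSE)
      expect_equal(mine$U, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("normal approximation handles ties and matches wilcox.test", {
  withr::local_seed(53)
  x <- c(rep(1, 10), rep(2, 15), rnorm(25, 1.5, 0.3))
  members <- sample(50, 12)
  mine <- mwu_term_test(x, members)
  ref <- wilcox.test(x[members], x[-members], exact = FALSE, correct = TRUE)
  expect_false(mine$exact)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  # degenerate all-equal measure
  expect_equal(mwu_term_test(rep(1, 30), 1:5)$p_value, 1)
})

test_that("Benjamini-Hochberg step-up matches the hand-computed example", {
  res <- bh_fdr(c(0.01, 0.02, 0.9))
  expect_equal(res$p_adjusted, c(0.03, 0.03, 0.9))
  expect_identical(res$significant, c(TRUE, TRUE, FALSE))
  single <- bh_fdr(0.05)
  expect_equal(single$p_adjusted, 0.05)
  expect_true(single$significant)
  # monotone in sorted order
  withr::local_seed(54)
  p <- runif(40)
  adj <- bh_fdr(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("enrichment recovers a planted term and respects domains", {
  withr::local_seed(55)
  genes <- paste0("g", 1:300)
  go <- simulate_go(genes, n_terms = 15, genes_per_term = 25,
                    planted = c(T01 = 2), seed = 56)
  measure <- setNames(rnorm(300), genes)
  shifted <- apply_planted_effects(measure, go$truth)
  planted_domain <- go$truth$domain[1]
  res <- run_enrichment(shifted, go$annotation, planted_domain)
  expect_identical(res$term[1], go$truth$term[1])
  expect_true(res$significant[1])
  expect_gt(res$delta_rank[1], 0)
  # tables are sorted by p and adjusted within the domain
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$p_adjusted >= res$p_value))

  # a domain with no annotations gives an empty result
  other <- setdiff(c("BP", "CC", "MF"), go$annotation$domain)
  if (length(other) == 0) {
    empty <- run_enrichment(shifted,
                            go$annotation[go$annotation$domain == "BP", ],
                            "MF")
    expect_equal(nrow(empty), 0L)
  }

  # shuffling gene labels destroys the planted association: the planted
  # term's evidence collapses by orders of magnitude (chance overlap with
  # the shifted values can still leave mild enrichment)
  shuffled <- setNames(sample(shifted), names(shifted))
  res_sh <- run_enrichment(shuffled, go$annotation, planted_domain)
  p_before <- res$p_value[res$term == go$truth$term[1]]
  p_after <- res_sh$p_value[res_sh$term == go$truth$term[1]]
  expect_lt(p_before, 1e-6)
  expect_gt(p_after, 1e3 * p_before)
})

test_that("terms below the minimum size are skipped", {
  genes <- paste0("g", 1:50)
  ann <- data.frame(gene_id = genes[1:3], term = "GO:0000001",
                    domain = "BP", stringsAsFactors = FALSE)
  measure <- setNames(seq_len(50), genes)
  expect_equal(nrow(run_enrichment(measure, ann, "BP", min_size = 5)), 0L)
  expect_equal(nrow(run_enrichment(measure, ann, "BP", min_size = 3)), 1L)
})
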