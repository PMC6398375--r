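test_that("zero-length branches leave descendants identical to the ancestor", {
  anc <- withr::with_seed(1, random_cds(50))
  tr <- simulate_codon_triplet(anc, c(internal = 0, A = 0, B = 0, C = 0),
                               omega = 0.5, seed = 2)
  expect_identical(tr$A, anc)
  expect_identical(tr$B, anc)
  expect_identical(tr$C, anc)
})

test_that("omega = 0 descendants differ from the ancestor only synonymously", {
  anc <- withr::with_seed(3, random_cds(200))
  tr <- simulate_codon_triplet(anc, c(internal = 0.1, A = 0.1, B = 0.1,
                                      C = 0.1), omega = 0, seed = 4)
  for (d in c(tr$A, tr$B, tr$C)) {
    expect_false(identical(d, anc))  # long branches: changes did occur
    expect_identical(translate_and_validate(d), translate_and_validate(anc))
  }
  expect_error(simulate_codon_triplet(anc, c(internal = 0.1, A = 0.1,
                                             B = 0.1, C = 0.1), omega = -1),
               "omega")
})

test_that("at omega = 1 acceptance does not distort the proposal ratio", {
  # oracle: the simulator's own proposal/acceptance counters
  anc <- withr::with_seed(5, random_cds(2000))
  tr <- simulate_codon_triplet(anc, c(internal = 0.1, A = 0.1, B = 0.1,
                                      C = 0.1), omega = 1, seed = 6)
  cnt <- tr$counters
  expect_equal(cnt[["acc_syn"]], cnt[["prop_syn"]])       # always accepted
  expect_equal(cnt[["acc_nonsyn"]], cnt[["prop_nonsyn"]]) # always accepted
  # and acceptance ratio tracks proposal ratio for omega = 0.5
  tr2 <- simulate_codon_triplet(anc, c(internal = 0.2, A = 0.2, B = 0.2,
                                       C = 0.2), omega = 0.5, seed = 7)
  c2 <- tr2$counters
  phat <- c2[["acc_nonsyn"]] / c2[["prop_nonsyn"]]
  se <- sqrt(0.5 * 0.5 / c2[["prop_nonsyn"]])
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("simulate_dataset is deterministic and honours paralog_rate", {
  p <- sim_params(n_genes = 12, seed = 42)
  p$paralog_rate <- 0
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$fasta, s2$fasta)
  expect_identical(s1$truth, s2$truth)
  expect_false(any(s1$truth$is_paralog))

  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_sim_dataset(s1, f1)
  write_sim_dataset(s2, f2)
  for (sp in c("HCAR", "HMAC", "HFLA"))
    expect_identical(readLines(file.path(f1, paste0(sp, "_cds.fasta"))),
                     readLines(file.path(f2, paste0(sp, "_cds.fasta"))))

  p2 <- sim_params(n_genes = 60, seed = 9)
  p2$paralog_rate <- 0.2
  s3 <- simulate_dataset(p2)
  expect_gt(sum(s3$truth$is_paralog), 0)
  expect_true(all(!is.na(s3$truth$contaminated_species[s3$truth$is_paralog])))
  # all emitted CDS are valid in-frame sequences
  for (sp in names(s3$fasta))
    for (id in names(s3$fasta[[sp]]))
      expect_silent(translate_and_validate(s3$fasta[[sp]][[id]], id))
})

test_that("paralog contaminants carry stochastically larger pairwise dS", {
  p <- sim_params(n_genes = 80, seed = 10)
  p$paralog_rate <- 0.25
  s <- simulate_dataset(p)
  mean_ds <- vapply(seq_len(nrow(s$truth)), function(g) {
    ids <- unlist(s$truth[g, c("HCAR", "HMAC", "HFLA")])
    prs <- combn(3, 2)
    mean(apply(prs, 2, function(pr) {
      a <- s$fasta[[pr[1]]][[ids[pr[1]]]]
      b <- s$fasta[[pr[2]]][[ids[pr[2]]]]
      ng86_pair(orthoselect:::split_codons(a),
                orthoselect:::split_codons(b))$dS
    }), na.rm = TRUE)
  }, numeric(1))
  con <- mean_ds[s$truth$is_paralog]
  ort <- mean_ds[!s$truth$is_paralog]
  expect_gt(min(con), quantile(ort, 0.9))  # clear stochastic separation
  expect_gt(median(con), 3 * median(ort))
})

test_that("simulate_go validates sizes and plants recoverable effects", {
  genes <- paste0("g", 1:50)
  expect_error(simulate_go(genes, genes_per_term = 60), "exceeds")
  go <- simulate_go(genes, n_terms = 9, genes_per_term = 10,
                    planted = c(T01 = 2), seed = 3)
  expect_setequal(unique(go$annotation$domain), c("BP", "CC", "MF"))
  expect_equal(go$truth$effect[1], 2)
  expect_true(all(go$truth$effect[-1] == 0))
  # planted effect shifts member measures into stochastic dominance
  withr::local_seed(4)
  measure <- setNames(rnorm(50), genes)
  shifted <- apply_planted_effects(measure, go$truth)
  members <- go$truth$members[[1]]
  w <- wilcox.test(shifted[members], shifted[setdiff(genes, members)],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
  # effect 0 terms leave the measure untouched
  expect_identical(shifted[setdiff(genes, members)],
                   measure[setdiff(genes, members)])
})

test_that("simulate_counts truth marks nulls and the outlier subgroup", {
  cs <- simulate_counts(n_genes = 300, de_fraction = 0.3,
                        outlier_subgroup = TRUE, seed = 5)
  lfc_cols <- grep("^lfc_", names(cs$truth))
  null_rows <- cs$truth$null
  expect_true(all(cs$truth[null_rows, lfc_cols] == 0))
  expect_true(any(cs$truth$is_marker))
  expect_equal(cs$outlier_samples,
               paste0("HFLA_s", 1:8))  # half of the 17 HFLA samples
  # marker genes are bimodal within HFLA: outlier samples hugely elevated
  m <- cs$counts[cs$truth$is_marker, , drop = FALSE]
  hfla_out <- colnames(m) %in% cs$outlier_samples
  hfla_in <- cs$meta$species == "HFLA" & !hfla_out
  expect_gt(median(m[, hfla_out]), 20 * median(m[, hfla_in]))
  # determinism
  cs2 <- simulate_counts(n_genes = 300, de_fraction = 0.3,
                         outlier_subgroup = TRUE, seed = 5)
  expect_identical(cs$counts, cs2$counts)
})
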