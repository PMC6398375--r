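test_that("single-codon site counts match the nine-mutant enumeration", {
  expect_equal(unname(ng86_sites("TTT")), c(8 / 3, 1 / 3))
  expect_equal(unname(ng86_sites("ATG")), c(3, 0))
  expect_error(ng86_sites("TAA"), "stop")
  withr::local_seed(31)
  for (cd in sample(orthoselect:::sense_codons(), 12)) {
    expect_equal(unname(ng86_sites(cd)), oracle_sites(cd))
    expect_equal(sum(ng86_sites(cd)), 3)
  }
})

test_that("pairwise counting matches pathway enumeration on single columns", {
  d <- ng86_pair("TTT", "TTA")
  expect_equal(d$Nd, 1); expect_equal(d$Sd, 0)
  expect_equal(d$N, 5 / 2); expect_equal(d$S, 1 / 2)
  expect_equal(d$pN, 0.4); expect_equal(d$pS, 0)

  d2 <- ng86_pair("GGG", "GGA")
  expect_equal(d2$Nd, 0); expect_equal(d2$Sd, 1)

  did <- ng86_pair(c("ATG", "TTT"), c("ATG", "TTT"))
  expect_equal(did$Nd, 0); expect_equal(did$Sd, 0)
  expect_equal(did$dN, 0); expect_equal(did$dS, 0)
  expect_identical(did$status, "ds_zero")
})

test_that("pairwise divergence is symmetric and JC-corrected upward", {
  withr::local_seed(32)
  sc <- orthoselect:::sense_codons()
  a <- sample(sc, 80, replace = TRUE)
  b <- sample(sc, 80, replace = TRUE)
  d1 <- ng86_pair(a, b)
  d2 <- ng86_pair(b, a)
  for (f in c("N", "S", "Nd", "Sd", "pN", "pS", "dN", "dS", "omega"))
    expect_equal(d1[[f]], d2[[f]])
  if (d1$status == "ok") {
    expect_gte(d1$dN, d1$pN)
    expect_gte(d1$dS, d1$pS)
  }
})

test_that("codon back-translation maps alignment columns to codons", {
  cds_a <- "ATGTTTGGG"
  cds_b <- "ATGGGG"
  # protein a = MFG, b = MG; align with a gap for F
  cal <- codon_align(cds_a, cds_b, list(a = "MFG", b = "M-G"))
  expect_equal(cal$dropped, 1)
  expect_identical(cal$codons_a, c("ATG", "GGG"))
  expect_identical(cal$codons_b, c("ATG", "GGG"))

  # identical CDS: nothing dropped
  cal2 <- codon_align(cds_a, cds_a, list(a = "MFG", b = "MFG"))
  expect_equal(cal2$dropped, 0)
  expect_equal(length(cal2$codons_a), 3)

  # mismatched alignment is rejected
  expect_error(codon_align(cds_a, cds_b, list(a = "MFG", b = "MGG")),
               "does not match")
})

test_that("kept plus dropped columns conserve both CDS", {
  withr::local_seed(33)
  for (rep in 1:5) {
    n <- 12
    a_cod <- sample(orthoselect:::sense_codons(), n, replace = TRUE)
    b_cod <- sample(orthoselect:::sense_codons(), n, replace = TRUE)
    cds_a <- paste(a_cod, collapse = "")
    cds_b <- paste(b_cod, collapse = "")
    pa <- translate_and_validate(cds_a)
    pb <- translate_and_validate(cds_b)
    # shifted global alignment: one flanking gap column in each sequence,
    # pairing a[i+1] with b[i]; all residue-residue columns are kept
    ga <- paste0(pa, "-")
    gb <- paste0("-", pb)
    cal <- codon_align(cds_a, cds_b, list(a = ga, b = gb))
    expect_equal(length(cal$codons_a) + 2 * 1, n + 1)  # n-1 kept, 2 gap cols
    expect_identical(cal$codons_a, a_cod[2:n])
    expect_identical(cal$codons_b, b_cod[1:(n - 1)])
  }
})

test_that("full-CDS divergence recovers simulated omega classes", {
  withr::local_seed(34)
  tree <- c(internal = 0.04, A = 0.04, B = 0.04, C = 0.1)
  om_p <- replicate(8, {
    tr <- simulate_codon_triplet(random_cds(250), tree, 0.2)
    ng86_cds(tr$A, tr$C)$omega
  })
  om_n <- replicate(8, {
    tr <- simulate_codon_triplet(random_cds(250), tree, 1.0)
    ng86_cds(tr$A, tr$C)$omega
  })
  expect_lt(median(om_p), 0.4)
  expect_gt(median(om_n), 0.7)
})

test_that("external divergence tables feed the downstream filters", {
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(pair = rep("HCAR_HMAC", 3),
                  gene_a = paste0("a", 1:3), gene_b = paste0("b", 1:3),
                  dN = c(0.02, 0.1, 0), dS = c(0.1, 0.05, 0))
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ext <- read_dnds(f)
  expect_equal(ext$omega, c(0.2, 2, NA))
  expect_identical(ext$status, c("ok", "ok", "ds_zero"))
  # filters accept the external omega values directly
  om <- setNames(ext$omega[ext$status == "ok"],
                 ext$gene_a[ext$status == "ok"])
  expect_warning(res <- omega_outlier_filter(om), "hard omega")
  expect_identical(res$positive, "a2")

  write.table(d[, -5], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dnds(f), "missing column")
})

test_that("selection classification applies the bounded positive call", {
  expect_identical(classify_selection(c(0.5, 1, 2, 3, 3.5)),
                   c("purifying", "neutral_boundary", "positive_candidate",
                     "excluded_high", "excluded_high"))
  expect_identical(classify_selection(2.9999), "positive_candidate")
  expect_error(classify_selection(NA_real_), "defined")
})
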