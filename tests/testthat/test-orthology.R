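test_that("hit acceptance applies the three thresholds strictly", {
  h <- function(ev, id, len) mk_hit("q", "s", ident = id, len = len,
                                    evalue = ev)
  expect_true(accept_hit(h(1e-6, 80, 60), subject_len = 100))
  expect_false(accept_hit(h(1e-6, 70, 60), subject_len = 100))
  expect_false(accept_hit(h(1e-6, 80, 50), subject_len = 100))  # >50% strict
  expect_false(accept_hit(h(1e-5, 80, 60), subject_len = 100))  # < strict
  expect_false(accept_hit(h(1e-6, 75, 60), subject_len = 100))  # > strict
  expect_error(accept_hit(h(1e-6, 80, 60), subject_len = 0), "positive")
})

# hand-built three-species hit universe: 2 genes per species; gene 1 forms a
# clean triplet, gene 2's HMAC-HFLA link is broken (HFLA side prefers g1)
toy_hits <- function() {
  sp <- c("HCAR", "HMAC", "HFLA")
  hits <- list()
  for (a in sp) for (b in sp) {
    if (a == b) next
    rows <- rbind(
      mk_hit(paste0(a, "_g1"), paste0(b, "_g1"), bitscore = 300),
      mk_hit(paste0(a, "_g2"), paste0(b, "_g2"), bitscore = 250))
    hits[[paste0(a, "_", b)]] <- rows
  }
  # break HFLA_g2 -> HMAC: its best hit becomes HMAC_g1
  h <- hits[["HFLA_HMAC"]]
  h$subject_id[h$query_id == "HFLA_g2"] <- "HMAC_g1"
  h$bitscore[h$query_id == "HFLA_g2"] <- 260
  hits[["HFLA_HMAC"]] <- h[order(h$query_id, -h$bitscore), ]
  hits
}

toy_lens <- function() {
  sp <- c("HCAR", "HMAC", "HFLA")
  lapply(setNames(sp, sp), function(s)
    setNames(c(120, 120), paste0(s, c("_g1", "_g2"))))
}

test_that("three-way RBB requires all three reciprocal links", {
  trip <- reciprocal_best_triplets(toy_hits(), toy_lens(), reference = "HMAC")
  expect_equal(nrow(trip), 1L)
  expect_equal(trip$HMAC, "HMAC_g1")
  expect_equal(trip$HCAR, "HCAR_g1")
  expect_equal(trip$HFLA, "HFLA_g1")

  hits <- toy_hits()
  hits[["HCAR_HMAC"]] <- NULL
  expect_error(reciprocal_best_triplets(hits, toy_lens()), "missing hit")
})

test_that("RBB pairs are symmetric under swapping the two hit tables", {
  hits <- toy_hits()
  lens <- toy_lens()
  p1 <- orthoselect:::rbb_pairs(hits[["HCAR_HMAC"]], hits[["HMAC_HCAR"]],
                                lens$HCAR, lens$HMAC)
  p2 <- orthoselect:::rbb_pairs(hits[["HMAC_HCAR"]], hits[["HCAR_HMAC"]],
                                lens$HMAC, lens$HCAR)
  expect_setequal(paste(p1$x, p1$y), paste(p2$y, p2$x))
})

test_that("best-hit tie-breaking is bitscore, then e-value, then subject id", {
  hits <- rbind(
    mk_hit("q", "s_b", bitscore = 200, evalue = 1e-30),
    mk_hit("q", "s_a", bitscore = 200, evalue = 1e-30),
    mk_hit("q", "s_c", bitscore = 210, evalue = 1e-20))
  lens <- setNames(rep(120, 3), c("s_a", "s_b", "s_c"))
  expect_identical(unname(orthoselect:::best_hits(hits, lens)), "s_c")
  hits$bitscore <- 200
  hits$evalue[3] <- 1e-10
  expect_identical(unname(orthoselect:::best_hits(hits, lens)), "s_a")
})

test_that("Markov clustering separates components and keeps columns stochastic", {
  # two disconnected triangles
  adj <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (tri in list(1:3, 4:6))
    for (i in tri) for (j in tri) if (i != j) adj[i, j] <- 1
  cl <- mcl_cluster(adj, inflation = 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)

  # single node
  one <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_equal(unname(mcl_cluster(one, inflation = 2)), 1L)

  expect_error(mcl_cluster(adj, inflation = 1), "inflation")
  expect_error(mcl_cluster(-adj, inflation = 2), ">= 0")
})

test_that("concordance retains only groups called by every method", {
  cand <- data.frame(HCAR = c("HCAR_g1", "HCAR_g2"),
                     HMAC = c("HMAC_g1", "HMAC_g2"),
                     HFLA = c("HFLA_g1", "HFLA_g2"),
                     ref_gene = c("HMAC_g1", "HMAC_g2"),
                     stringsAsFactors = FALSE)
  clusters <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                       c("HCAR_g1", "HMAC_g1", "HFLA_g1",
                         "HCAR_g2", "HMAC_g2", "HFLA_g2"))
  res <- concordance_filter(cand, c(TRUE, TRUE), clusters)
  expect_true(all(res$groups$retained))
  expect_equal(res$retention_fraction, 1)

  res2 <- concordance_filter(cand, c(TRUE, FALSE), clusters)
  expect_identical(res2$groups$retained, c(TRUE, FALSE))

  # members split across clusters are not retained
  clusters2 <- clusters
  clusters2["HFLA_g1"] <- 3L
  res3 <- concordance_filter(cand, c(TRUE, TRUE), clusters2)
  expect_identical(res3$groups$retained, c(FALSE, TRUE))
})

test_that("similarity graph has symmetric capped weights and self-loops", {
  hits <- list(mk_hit("a", "b", evalue = 1e-300),
               mk_hit("b", "c", evalue = 1e-10))
  g <- build_similarity_graph(hits, c("a", "b", "c", "lone"))
  expect_equal(g["a", "b"], 200)     # capped
  expect_equal(g["b", "a"], 200)
  expect_equal(g["b", "c"], 10)
  expect_equal(g["a", "a"], 200)     # node max self-loop
  expect_equal(g["lone", "lone"], 1) # isolated node
})
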