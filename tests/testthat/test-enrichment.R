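test_that("hypergeometric enrichment matches hand calculation and the oracle", {
  universe <- sprintf("U%02d", 1:20)
  sets <- gene_set_collection(list(FULL = universe[1:5],
                                   MISS = universe[11:15]))
  res <- fisher_enrich(universe[1:5], universe, sets)
  # perfect 5-of-5 overlap: p = 1 / C(20,5)
  expect_equal(res$p[res$term == "FULL"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p[res$term == "MISS"], 1)  # k = 0 reported with p = 1

  # combined score from the hypergeometric moments
  ex <- 5 * 5 / 20
  vx <- 5 * 5 * 15 * 15 / (20^2 * 19)
  z <- (5 - ex) / sqrt(vx)
  expect_equal(res$zscore[res$term == "FULL"], z)
  expect_equal(res$combined_score[res$term == "FULL"],
               -log(1 / choose(20, 5)) * z)

  # query == universe makes every term certain
  res_all <- fisher_enrich(universe, universe, sets)
  expect_true(all(res_all$p == 1))

  expect_error(fisher_enrich(character(0), universe, sets), "empty")
  expect_warning(fisher_enrich(c(universe[1:3], "NOT_THERE"), universe, sets),
                 "outside")
})

test_that("tail probabilities agree with brute-force summation on random configs", {
  set.seed(77)
  for (i in 1:100) {
    N <- sample(20:2000, 1)
    K <- sample.int(N - 1, 1)
    n <- sample.int(N - 1, 1)
    k <- sample(0:min(K, n), 1)
    p_pkg <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_oracle <- oracle_hyper_tail(k, N, K, n)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
})

test_that("combined score behaves monotonically and at its fixed points", {
  # p = 1 gives zero score regardless of z; z = 0 gives zero score
  expect_equal(combined_score(1, 3.2), 0)
  expect_equal(combined_score(0.001, 0), 0)
  # monotone decreasing in p at fixed positive z
  ps <- c(0.5, 0.1, 0.01, 1e-6)
  cs <- vapply(ps, combined_score, 0, zscore = 2)
  expect_false(is.unsorted(cs))
  expect_warning(c0 <- combined_score(0, 1), "clamped")
  expect_true(is.finite(c0))
})

test_that("a planted enriched term ranks first in nearly all seeds", {
  first <- 0L
  n_seeds <- 20L
  for (i in seq_len(n_seeds)) {
    set.seed(800 + i)
    universe <- sprintf("G%04d", 1:1000)
    query <- sample(universe, 100)
    sets <- generate_gene_sets(universe, n_sets = 50,
                               set_size_range = c(10, 50),
                               planted_set = sample(query, 20),
                               seed = 800 + i)
    res <- fisher_enrich(query, universe, sets)
    if (res$term[which.min(res$padj)] == "PLANTED_TERM") first <- first + 1L
  }
  expect_gte(first / n_seeds, 0.95)
})

test_that("term clustering groups by overlap similarity deterministically", {
  rows <- data.frame(term = c("T1", "T2", "T3"),
                     padj = c(0.01, 0.02, 0.03),
                     stringsAsFactors = FALSE)
  rows$overlap_genes <- I(list(c("A", "B", "C"), c("A", "B", "C"),
                               c("X", "Y")))
  cl <- cluster_terms(rows)
  expect_equal(cl$clusters[["T1"]], cl$clusters[["T2"]]) # identical overlaps
  expect_false(cl$clusters[["T1"]] == cl$clusters[["T3"]]) # disjoint
  expect_equal(unname(cl$representatives[as.character(cl$clusters[["T1"]])]),
               "T1")

  # average-linkage merge: A~B=.8, B~C=.8, A~C=.7 -> one cluster at 0.5
  mk <- function(n) sprintf("g%02d", n)
  rows2 <- data.frame(term = c("A", "B", "C"), padj = c(0.01, 0.02, 0.03))
  rows2$overlap_genes <- I(list(mk(1:9), mk(c(1:8, 10)), mk(c(1:7, 10, 11))))
  jac <- cluster_terms(rows2)$similarity
  expect_equal(jac["A", "B"], 8 / 10)
  cl2 <- cluster_terms(rows2, similarity_threshold = 0.5)
  expect_equal(length(unique(cl2$clusters)), 1L)

  # permuting input order changes labels only, not the partition
  perm <- c(3, 1, 2)
  cl_perm <- cluster_terms(rows2[perm, ], similarity_threshold = 0.5)
  same_cluster <- function(cl, a, b) cl$clusters[[a]] == cl$clusters[[b]]
  for (pair in list(c("A", "B"), c("B", "C"), c("A", "C"))) {
    expect_equal(same_cluster(cl2, pair[1], pair[2]),
                 same_cluster(cl_perm, pair[1], pair[2]))
  }
})

test_that("venn summaries count shared and exclusive DEGs exactly", {
  v <- venn_overlap(list(
    MSAP = list(up = c("u1", "u2"), down = c("g1", "g2", "g3")),
    PD = list(up = c("u2", "u3"), down = c("g2", "g3", "g4"))
  ))
  expect_equal(v$down$shared, 2)
  expect_equal(v$down$shared_genes, c("G2", "G3"))
  expect_equal(unname(v$down$exclusive), c(1L, 1L))
  expect_equal(unname(v$down$pct_of_directional), c(200 / 3, 200 / 3))
  expect_equal(unname(v$down$pct_of_total), c(40, 40))
  expect_equal(v$up$shared, 1)

  # disjoint and identical edge cases
  v2 <- venn_overlap(list(A = list(up = "x", down = "a"),
                          B = list(up = "y", down = "b")))
  expect_equal(v2$down$shared, 0)
  ten <- sprintf("d%02d", 1:10)
  v3 <- venn_overlap(list(A = list(up = character(0), down = ten),
                          B = list(up = character(0), down = ten)))
  expect_equal(v3$down$shared, 10)
  expect_equal(unname(v3$down$pct_of_directional), c(100, 100))

  expect_warning(venn_overlap(list(A = list(up = "x", down = c("a", "a")),
                                   B = list(up = "y", down = "b"))),
                 "duplicate")
})
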