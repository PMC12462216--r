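test_that("column normalization yields a stochastic matrix with self-loops on isolates", {
  g <- igraph::make_graph(~ A - B, B - C)
  W <- column_normalize(g)
  expect_equal(as.numeric(W[, "B"]), c(0.5, 0, 0.5))
  expect_equal(unname(Matrix::colSums(W)), rep(1, 3))

  # a regular graph's normalized adjacency is symmetric and unchanged by
  # renormalization
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("N", 1:6)
  W2 <- column_normalize(ring)
  expect_equal(as.matrix(W2), t(as.matrix(W2)))

  # isolated node becomes an identity column
  g3 <- igraph::make_graph(~ A - B) + igraph::vertices("LONER")
  W3 <- column_normalize(g3)
  expect_equal(as.numeric(W3[, "LONER"]), c(0, 0, 1))
  expect_equal(unname(Matrix::colSums(W3)), rep(1, 3))
})

test_that("seed vectors place normalized fold-change mass on mapped DEGs", {
  g <- igraph::make_graph(~ A - B, B - C, C - D)
  de <- data.frame(gene = c("A", "C", "ZZZ"),
                   log2FC = c(-3, 1, 5),
                   padj = c(0.01, 0.01, 0.01))
  expect_warning(p0 <- build_seed_vector(de, g), "ZZZ")
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0[c("A", "C")]), c(3, 1) / 4)
  expect_equal(unname(p0[c("B", "D")]), c(0, 0))

  # single DEG gets unit mass regardless of sign
  de1 <- data.frame(gene = "B", log2FC = -3, padj = 0.001)
  expect_equal(unname(build_seed_vector(de1, g)["B"]), 1)

  # equal magnitudes split evenly under the abs transform
  de2 <- data.frame(gene = c("A", "B"), log2FC = c(1, -1), padj = 0.01)
  expect_equal(unname(build_seed_vector(de2, g)[c("A", "B")]), c(0.5, 0.5))

  # nothing mappable is an error listing symbols
  de3 <- data.frame(gene = "ZZZ", log2FC = 2, padj = 0.01)
  expect_error(suppressWarnings(build_seed_vector(de3, g)), "ZZZ")

  # signed-split returns one normalized vector per direction
  ps <- suppressWarnings(build_seed_vector(de, g, transform = "signed-split"))
  expect_equal(unname(colSums(ps)), c(1, 1))
  expect_equal(unname(ps["C", "up"]), 1)
  expect_equal(unname(ps["A", "down"]), 1)
})

test_that("RWR matches the hand-derived two-node solution and the restart limit", {
  g <- igraph::make_graph(~ A - B)
  W <- column_normalize(g)
  p <- rwr(W, c(1, 0), r = 0.5)
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3), tolerance = 1e-7)

  # r -> 1: restart dominates and p stays at the seed
  p_hi <- rwr(W, c(1, 0), r = 0.999)
  expect_lt(sum(abs(p_hi - c(1, 0))), 0.01)
})

test_that("iterative RWR agrees with the closed-form solve and conserves mass", {
  set.seed(101)
  for (i in 1:20) {
    g <- random_connected_graph(sample(5:50, 1))
    W <- column_normalize(g)
    n <- nrow(W)
    p0 <- numeric(n)
    seeds <- sample.int(n, sample(1:5, 1))
    p0[seeds] <- runif(length(seeds))
    p0 <- p0 / sum(p0)
    r <- runif(1, 0.3, 0.9)
    p <- rwr(W, p0, r = r, tol = 1e-12)
    expect_lt(max(abs(p - oracle_rwr(W, p0, r))), 1e-8)
    expect_lt(max(abs(attr(p, "mass_history") - 1)), 1e-9)
    expect_lt(attr(p, "residual"), 1e-11 * 10)
  }
})

test_that("seed mass added to a node never decreases its stationary probability", {
  set.seed(202)
  for (i in 1:10) {
    g <- random_connected_graph(20)
    W <- column_normalize(g)
    p0 <- rep(1 / 20, 20)
    target <- sample.int(20, 1)
    p0_boost <- p0
    p0_boost[target] <- p0_boost[target] + 0.5
    p0_boost <- p0_boost / sum(p0_boost)
    p_base <- rwr(W, p0, r = 0.7, tol = 1e-12)
    p_boost <- rwr(W, p0_boost, r = 0.7, tol = 1e-12)
    expect_gte(p_boost[target], p_base[target] - 1e-12)
  }
})

test_that("betweenness matches closed forms, the enumeration oracle and igraph", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("HUB", "L1", "L2", "L3")
  expect_equal(unname(betweenness_centrality(star)), c(3, 0, 0, 0))
  expect_equal(unname(betweenness_centrality(star, normalized = TRUE)),
               c(1, 0, 0, 0))

  set.seed(303)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    g <- random_connected_graph(n, extra_edges = sample(0:4, 1))
    bc <- betweenness_centrality(g)
    expect_equal(unname(bc), oracle_betweenness(g), tolerance = 1e-12)
    expect_equal(unname(bc), unname(igraph::betweenness(g)),
                 tolerance = 1e-10)
  }

  # disconnected pairs contribute zero
  two_comps <- igraph::make_graph(~ A - B, B - C, X - Y)
  expect_equal(unname(betweenness_centrality(two_comps)),
               c(0, 1, 0, 0, 0))
})

test_that("key genes require both high propagation and high betweenness", {
  res <- data.frame(
    gene = c("HUB", "LEAF", paste0("G", 1:10)),
    probability = c(0.30, 0.25, seq(0.2, 0.02, length.out = 10)),
    betweenness = c(50, 0, seq(40, 4, length.out = 10)),
    is_deg = TRUE
  )
  out <- select_key_genes(res, 0.9, 0.9)
  expect_true(out$key[out$gene == "HUB"])
  # top probability but zero betweenness fails the joint criterion
  expect_false(out$key[out$gene == "LEAF"])
  # ranked by probability descending
  expect_equal(out$gene[1], "HUB")
  expect_false(is.unsorted(rev(out$probability)))

  # degenerate thresholds flag every DEG; non-DEGs never flagged
  res$is_deg[3] <- FALSE
  out0 <- suppressWarnings(select_key_genes(res, 0, 0))
  expect_true(all(out0$key[out0$is_deg]))
  expect_false(any(out0$key[!out0$is_deg]))

  expect_warning(select_key_genes(res[1:3, ], 0.9, 0.9), "fewer than 10")
})

test_that("end-to-end propagation flags planted hubs and reports diagnostics", {
  sim <- tiny_two_group(n_genes = 400, n_per = 10, seed = 61, frac_de = 0.15,
                        effect = 2.5)
  de <- nb_wald_test(sim$counts, sim$meta, c("PD", "HC"))
  ppi <- generate_ppi(200, 2, seed = 61, genes = rownames(sim$counts))
  prop <- suppressWarnings(propagate_degs(de, ppi, alpha = 0.05))
  expect_setequal(names(prop),
                  c("gene", "log2FC", "seed", "probability", "betweenness",
                    "is_deg", "key"))
  expect_equal(sum(prop$probability), 1, tolerance = 1e-9)
  expect_equal(sum(prop$seed), 1, tolerance = 1e-12)
  expect_true(all(prop$betweenness >= 0))
  expect_true(all(prop$key <= prop$is_deg))  # key => DEG
  expect_lt(attr(prop, "rwr_residual"), 1e-7)
})
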