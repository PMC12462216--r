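# Independent oracles used across the suite. They deliberately share no code
# with the package: betweenness by exhaustive simple-path enumeration, the
# hypergeometric tail by direct log-binomial summation, RWR by a dense
# linear solve.

# all-pairs shortest-path enumeration betweenness (feasible for n <= ~8)
oracle_betweenness <- function(g, normalized = FALSE) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  enumerate_paths <- function(s, t) {
    paths <- list()
    rec <- function(v, visited) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- visited
        return(invisible(NULL))
      }
      for (w in adj[[v]]) if (!(w %in% visited)) rec(w, c(visited, w))
    }
    rec(s, s)
    paths
  }
  bc <- numeric(n)
  if (n < 3L) return(bc)
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      paths <- enumerate_paths(s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, 0L)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
        bc[v] <- bc[v] + through / sigma
      }
    }
  }
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# hypergeometric upper tail P(X >= k) by direct summation on the log scale
oracle_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# dense closed-form RWR: p = r (I - (1 - r) W)^{-1} p0
oracle_rwr <- function(W, p0, r) {
  n <- nrow(W)
  as.numeric(solve(diag(n) - (1 - r) * as.matrix(W), r * p0))
}

# random connected simple undirected graph: a random spanning tree plus
# random extra edges
random_connected_graph <- function(n, extra_edges = n) {
  stopifnot(n >= 2)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  if (extra_edges > 0L) {
    more <- cbind(sample.int(n, extra_edges, replace = TRUE),
                  sample.int(n, extra_edges, replace = TRUE))
    more <- more[more[, 1L] != more[, 2L], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("N", seq_len(n))
  g
}

# small count fixture with two groups of n_per ROIs each
tiny_two_group <- function(n_genes = 200, n_per = 6, seed = 1, frac_de = 0,
                           effect = 2, dispersion = 0.1,
                           unwanted_sigma = 0) {
  cfg <- simulation_config(
    n_genes = n_genes, n_subjects_per_group = 1L, rois_per_subject = n_per,
    groups = c("HC", "PD"), frac_de = frac_de, effect_log2fc = effect,
    nb_dispersion = dispersion, unwanted_sigma = unwanted_sigma,
    n_control_genes = 0L, seed = seed
  )
  generate_dataset(cfg)
}
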