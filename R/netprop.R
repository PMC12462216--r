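#' Column-normalize a network adjacency matrix
#'
#' Builds the column-stochastic transition matrix `W'` of a random walk on
#' the network: `W'_ij = A_ij / sum_i A_ij`. Zero-degree columns (isolated
#' nodes) receive a self-loop, i.e. become identity columns, which preserves
#' column-stochasticity without teleporting their mass.
#'
#' @param network an `igraph` graph (undirected; names used as labels) or a
#'   symmetric 0/1 adjacency matrix.
#' @return a sparse column-stochastic `dgCMatrix` with node dimnames.
#' @export
column_normalize <- function(network) {
  A <- if (inherits(network, "igraph")) {
    if (igraph::vcount(network) == 0L) stop("empty network")
    igraph::as_adjacency_matrix(network, sparse = TRUE)
  } else {
    if (nrow(network) == 0L) stop("empty network")
    methods::as(methods::as(as.matrix(network), "dMatrix"), "CsparseMatrix")
  }
  deg <- Matrix::colSums(A)
  isolated <- which(deg == 0)
  if (length(isolated) > 0L) {
    A[cbind(isolated, isolated)] <- 1
    deg[isolated] <- 1
  }
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- list(rownames(A), rownames(A))
  W
}

#' Build the RWR seed vector from a differential-expression table
#'
#' Significant DEGs (`padj < alpha`) that map onto the network by symbol are
#' seeded with a transform of their log2 fold change; all other nodes get 0;
#' the vector is rescaled to sum 1 so it is a probability distribution.
#' Unmapped DEGs are reported with a warning.
#'
#' @param de DE result table (columns `gene`, `log2FC`, `padj`).
#' @param network `igraph` graph with named vertices.
#' @param transform `"abs"` (default, |log2FC|), `"positive-part"`
#'   (`max(log2FC, 0)`, i.e. upregulated mass only), or `"signed-split"`
#'   (returns a two-column matrix with separate `up` and `down` seed
#'   vectors, each summing to 1).
#' @param alpha significance threshold on adjusted p.
#' @return named numeric vector summing to 1 over network nodes (or a
#'   two-column matrix for `"signed-split"`).
#' @export
build_seed_vector <- function(de, network,
                              transform = c("abs", "positive-part",
                                            "signed-split"),
                              alpha = 0.05) {
  transform <- match.arg(transform)
  nodes <- igraph::V(network)$name
  sig <- de[is.finite(de$padj) & de$padj < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant DEGs to seed")
  mapped <- sig$gene %in% nodes
  if (any(!mapped)) {
    warning(sum(!mapped), " significant DEG(s) absent from the network: ",
            paste(utils::head(sig$gene[!mapped], 5L), collapse = ", "))
  }
  sig <- sig[mapped, , drop = FALSE]
  if (nrow(sig) == 0L) {
    stop("zero mappable DEGs; symbols tried: ",
         paste(utils::head(de$gene[de$padj < alpha], 10L), collapse = ", "))
  }
  make_vec <- function(vals, genes) {
    p0 <- stats::setNames(numeric(length(nodes)), nodes)
    p0[genes] <- vals
    total <- sum(p0)
    if (total <= 0) stop("seed vector has no positive mass")
    p0 / total
  }
  switch(transform,
    "abs" = make_vec(abs(sig$log2FC), sig$gene),
    "positive-part" = {
      up <- sig[sig$log2FC > 0, , drop = FALSE]
      if (nrow(up) == 0L) stop("no upregulated DEGs for positive-part seeding")
      make_vec(up$log2FC, up$gene)
    },
    "signed-split" = {
      up <- sig[sig$log2FC > 0, , drop = FALSE]
      down <- sig[sig$log2FC < 0, , drop = FALSE]
      if (nrow(up) == 0L || nrow(down) == 0L) {
        stop("signed-split needs both up- and downregulated DEGs")
      }
      cbind(up = make_vec(up$log2FC, up$gene),
            down = make_vec(abs(down$log2FC), down$gene))
    }
  )
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - r) W' p_t + r p0` from `p_0 = p0` until the L1
#' change drops below `tol`. On a column-stochastic `W'` the walk conserves
#' total mass at every iteration, and the returned vector satisfies the
#' fixed point `p = (1 - r) W' p + r p0` within `10 * tol`.
#'
#' @param W column-stochastic transition matrix (see [column_normalize()]).
#' @param p0 seed probability vector summing to 1.
#' @param r restart rate, strictly inside (0, 1). Default 0.7.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; reaching it is an error reporting the
#'   final residual (cannot happen for `r > 0` on a stochastic matrix, the
#'   map is a contraction with factor `1 - r`).
#' @return named stationary probability vector with attributes
#'   `iterations`, `residual` (final fixed-point L1 residual) and
#'   `mass_history` (total mass after every iteration).
#' @export
rwr <- function(W, p0, r = 0.7, tol = 1e-8, max_iter = 10000L) {
  stopifnot(r > 0, r < 1, tol > 0)
  n <- nrow(W)
  stopifnot(length(p0) == n, all(p0 >= 0))
  if (abs(sum(p0) - 1) > 1e-6) stop("seed vector must sum to 1")
  p <- as.numeric(p0)
  mass <- numeric(0)
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - r) * (W %*% p) + r * p0)
    mass <- c(mass, sum(p_new))
    if (sum(abs(p_new - p)) < tol) {
      res <- sum(abs(p_new - ((1 - r) * as.numeric(W %*% p_new) + r * p0)))
      out <- stats::setNames(p_new, rownames(W))
      attr(out, "iterations") <- it
      attr(out, "residual") <- res
      attr(out, "mass_history") <- mass
      return(out)
    }
    p <- p_new
  }
  stop("RWR failed to converge in ", max_iter,
       " iterations; final L1 change ", format(sum(abs(p_new - p))))
}

#' Betweenness centrality (Brandes accumulation)
#'
#' `BC(v) = sum_{s != v != t} sigma_st(v) / sigma_st`, where `sigma_st`
#' counts shortest paths between `s` and `t` and `sigma_st(v)` those passing
#' through `v`. Uses Brandes' single-source accumulation with the undirected
#' convention (each unordered pair counted once); disconnected pairs
#' contribute 0. Optionally normalized by `(n - 1)(n - 2) / 2`.
#'
#' @param network `igraph` graph (undirected, named).
#' @param normalized divide by the number of unordered pairs excluding `v`.
#' @return named numeric vector of nonnegative centralities.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  adj <- igraph::as_adj_list(network, mode = "all")
  adj <- lapply(adj, as.integer)
  bc <- numeric(n)
  queue <- integer(n)  # preallocated BFS queue; visit order = dequeue order
  for (s in seq_len(n)) {
    # BFS from s with shortest-path counting
    sigma <- numeric(n); sigma[s] <- 1
    dist_s <- rep(-1L, n); dist_s[s] <- 0L
    preds <- vector("list", n)
    queue[1L] <- s
    head_q <- 1L; tail_q <- 1L
    while (head_q <= tail_q) {
      v <- queue[head_q]; head_q <- head_q + 1L
      for (w in adj[[v]]) {
        if (dist_s[w] < 0L) {
          dist_s[w] <- dist_s[v] + 1L
          tail_q <- tail_q + 1L
          queue[tail_q] <- w
        }
        if (dist_s[w] == dist_s[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse visit order
    delta <- numeric(n)
    for (i in seq.int(tail_q, 1L)) {
      w <- queue[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair was accumulated from both endpoints
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    bc <- if (denom > 0) bc / denom else bc * 0
  }
  stats::setNames(bc, igraph::V(network)$name)
}

#' Network propagation of significant DEGs on a PPI network
#'
#' End-to-end convenience for the hub-gene stage: builds the seed vector
#' from significant DEGs, runs the random walk with restart on the
#' column-normalized PPI adjacency, computes betweenness centrality on the
#' network's largest connected component, and flags key genes.
#'
#' @inheritParams build_seed_vector
#' @inheritParams rwr
#' @inheritParams select_key_genes
#' @param component `"largest"` (default) restricts betweenness and
#'   propagation to the largest connected component; `"full"` uses the whole
#'   network.
#' @return a `PropagationResult` data frame: `gene`, `log2FC` (NA for
#'   non-DEG nodes), `seed`, `probability`, `betweenness`, `is_deg`, `key`,
#'   sorted by probability descending (ties: betweenness, then symbol).
#' @export
propagate_degs <- function(de, network, transform = "abs", alpha = 0.05,
                           r = 0.7, tol = 1e-8, max_iter = 10000L,
                           prob_quantile = 0.90, bc_quantile = 0.90,
                           component = c("largest", "full")) {
  component <- match.arg(component)
  if (component == "largest") {
    comp <- igraph::components(network)
    keep <- which(comp$membership == which.max(comp$csize))
    network <- igraph::induced_subgraph(network, keep)
  }
  W <- column_normalize(network)
  p0 <- build_seed_vector(de, network, transform = transform, alpha = alpha)
  if (is.matrix(p0)) {
    stop("signed-split seeding returns two vectors; run rwr() on each ",
         "column directly")
  }
  p <- rwr(W, p0, r = r, tol = tol, max_iter = max_iter)
  bc <- betweenness_centrality(network, normalized = FALSE)
  nodes <- igraph::V(network)$name
  lfc <- de$log2FC[match(nodes, de$gene)]
  res <- data.frame(
    gene = nodes,
    log2FC = lfc,
    seed = as.numeric(p0),
    probability = as.numeric(p),
    betweenness = as.numeric(bc[nodes]),
    is_deg = as.numeric(p0) > 0,
    stringsAsFactors = FALSE
  )
  res <- select_key_genes(res, prob_quantile = prob_quantile,
                          bc_quantile = bc_quantile)
  attr(res, "rwr_residual") <- attr(p, "residual")
  attr(res, "rwr_iterations") <- attr(p, "iterations")
  res
}

#' Flag key hub genes by joint propagation and betweenness criteria
#'
#' A node is key iff it is a seeded significant DEG and both its stationary
#' probability and its betweenness reach the given quantiles computed over
#' the DEG nodes. Output is ranked by probability descending, ties broken by
#' betweenness descending then symbol.
#'
#' @param result propagation result data frame (columns `gene`,
#'   `probability`, `betweenness`, `is_deg`).
#' @param prob_quantile,bc_quantile quantile thresholds in \[0, 1\] applied
#'   to the DEG nodes' probabilities and betweenness values. 0 flags every
#'   seeded DEG.
#' @return the input with a logical `key` column, re-sorted.
#' @export
select_key_genes <- function(result, prob_quantile = 0.90,
                             bc_quantile = 0.90) {
  stopifnot(all(c("gene", "probability", "betweenness", "is_deg")
                %in% names(result)))
  degs <- result[result$is_deg, , drop = FALSE]
  if (nrow(degs) < 10L) {
    warning("fewer than 10 DEG nodes; key-gene quantiles are unstable")
  }
  p_thr <- as.numeric(quantile(degs$probability, prob_quantile, names = FALSE))
  b_thr <- as.numeric(quantile(degs$betweenness, bc_quantile, names = FALSE))
  result$key <- result$is_deg &
    result$probability >= p_thr &
    result$betweenness >= b_thr
  ord <- order(-result$probability, -result$betweenness, result$gene)
  result <- result[ord, , drop = FALSE]
  rownames(result) <- NULL
  result
}
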