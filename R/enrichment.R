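#' Over-representation analysis against a gene-set collection
#'
#' For each term the overlap of the query with the term (both intersected
#' with the universe first) is scored with the hypergeometric upper-tail
#' probability `P(X >= k | N, K, n)`, adjusted across terms by
#' Benjamini-Hochberg, and ranked with an Enrichr-style combined score
#' `c = -ln(p) * z`, where `z` is the hypergeometric standardized deviation
#' `(k - E[X]) / sd(X)`. Terms with no overlap are reported with `p = 1`.
#'
#' @param query character vector of (DEG) gene symbols; genes outside the
#'   universe are dropped with a warning; an empty query is an error.
#' @param universe character vector of all testable genes (>= 2).
#' @param sets a [gene_set_collection()].
#' @return data frame with one row per term: `term`, `k` (overlap), `K`
#'   (set size in universe), `n` (query size), `N` (universe size), `p`,
#'   `padj`, `zscore`, `combined_score`, and list column `overlap_genes`;
#'   sorted by `p` ascending.
#' @export
fisher_enrich <- function(query, universe, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(canonical_symbols(universe))
  if (length(universe) < 2L) stop("universe needs at least 2 genes")
  query <- unique(canonical_symbols(query))
  if (length(query) == 0L) stop("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "))
    query <- setdiff(query, outside)
    if (length(query) == 0L) stop("no query genes left inside the universe")
  }
  N <- as.numeric(length(universe))
  n <- as.numeric(length(query))
  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], universe)
    K <- as.numeric(length(members))
    overlap <- intersect(query, members)
    k <- length(overlap)
    p <- if (k == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ex <- n * K / N
    vx <- n * K * (N - K) * (N - n) / (N^2 * (N - 1))
    z <- if (vx > 0) (k - ex) / sqrt(vx) else 0
    list(term = term, k = k, K = K, overlap = overlap, p = p, z = z)
  })
  df <- data.frame(
    term = vapply(rows, `[[`, "", "term"),
    k = vapply(rows, `[[`, 0L, "k"),
    K = as.integer(vapply(rows, `[[`, 0, "K")),
    n = n,
    N = N,
    p = vapply(rows, `[[`, 0, "p"),
    zscore = vapply(rows, `[[`, 0, "z"),
    stringsAsFactors = FALSE
  )
  df$padj <- bh_adjust(df$p)
  df$combined_score <- mapply(combined_score, df$p, df$zscore)
  df$overlap_genes <- I(lapply(rows, `[[`, "overlap"))
  df <- df[order(df$p, df$term),
           c("term", "k", "K", "n", "N", "p", "padj", "zscore",
             "combined_score", "overlap_genes")]
  rownames(df) <- NULL
  df
}

#' Enrichr-style combined score
#'
#' `c = -ln(p) * z`. The z-score here is the hypergeometric standardized
#' deviation of the overlap, so `c >= 0` whenever the overlap exceeds its
#' expectation; this deviates from Enrichr's rank-corrected z (whose random-
#' set reference tables are not reproducible), so printed Enrichr combined
#' scores are not comparable values.
#'
#' @param p enrichment p-value in (0, 1\]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @param zscore deviation score.
#' @return numeric combined score.
#' @export
combined_score <- function(p, zscore) {
  stopifnot(length(p) == 1L, length(zscore) == 1L, p >= 0, p <= 1)
  if (p == 0) {
    warning("p = 0 clamped to smallest representable positive double")
    p <- .Machine$double.xmin
  }
  -log(p) * zscore
}

#' Cluster enriched terms by overlap-gene similarity
#'
#' Redundancy reduction for enrichment output: pairwise Jaccard similarity
#' of the terms' overlap gene sets, average-linkage hierarchical clustering,
#' cut at distance `1 - similarity_threshold`. Each cluster's representative
#' is its lowest-padj term.
#'
#' @param rows output of [fisher_enrich()] (needs `term`, `padj`,
#'   `overlap_genes`).
#' @param similarity_threshold Jaccard similarity at/above which terms are
#'   merged (default 0.5).
#' @return list with `clusters` (named integer vector term -> cluster id),
#'   `representatives` (one term per cluster, lowest padj), and `similarity`
#'   (the Jaccard matrix, heatmap-ready).
#' @export
cluster_terms <- function(rows, similarity_threshold = 0.5) {
  stopifnot(nrow(rows) >= 1L)
  sets <- lapply(rows$overlap_genes, unique)
  m <- length(sets)
  jac <- matrix(1, m, m, dimnames = list(rows$term, rows$term))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        u <- length(union(sets[[i]], sets[[j]]))
        jac[i, j] <- jac[j, i] <-
          if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  if (m == 1L) {
    cl <- stats::setNames(1L, rows$term)
  } else {
    hc <- hclust(stats::as.dist(1 - jac), method = "average")
    cl <- cutree(hc, h = 1 - similarity_threshold)
    names(cl) <- rows$term
  }
  reps <- vapply(split(seq_len(m), cl), function(idx) {
    rows$term[idx[which.min(rows$padj[idx])]]
  }, "")
  list(clusters = cl, representatives = reps, similarity = jac)
}

#' Directional DEG overlap (Venn) summary across comparisons
#'
#' For two or more labelled comparisons, each providing an up- and a
#' down-regulated gene list, counts the genes shared by all comparisons and
#' exclusive to each, per direction. Shared percentages are reported with
#' two denominator conventions: the comparison's directional list size, and
#' its total DEG count (up + down).
#'
#' @param lists named list; each element is a list with character vectors
#'   `up` and `down`. Duplicates within a list are removed with a warning.
#' @return object of class `"venn_summary"`: per direction, `shared_genes`,
#'   `shared` count, `exclusive` counts per label, `pct_of_directional` and
#'   `pct_of_total` per label (in percent).
#' @export
venn_overlap <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L, !is.null(names(lists)))
  labels <- names(lists)
  lists <- lapply(labels, function(lab) {
    l <- lists[[lab]]
    stopifnot(all(c("up", "down") %in% names(l)))
    lapply(l[c("up", "down")], function(g) {
      g <- canonical_symbols(g)
      if (anyDuplicated(g)) {
        warning("duplicate genes in list '", lab, "' deduplicated")
        g <- unique(g)
      }
      g
    })
  })
  names(lists) <- labels
  totals <- vapply(lists, function(l) length(l$up) + length(l$down), 0L)
  out <- lapply(c(up = "up", down = "down"), function(dir) {
    gl <- lapply(lists, `[[`, dir)
    shared <- Reduce(intersect, gl)
    exclusive <- vapply(seq_along(gl), function(i) {
      length(setdiff(gl[[i]], Reduce(union, gl[-i])))
    }, 0L)
    names(exclusive) <- labels
    list(
      shared_genes = sort(shared),
      shared = length(shared),
      exclusive = exclusive,
      pct_of_directional = stats::setNames(
        100 * length(shared) / pmax(vapply(gl, length, 0L), 1L), labels),
      pct_of_total = stats::setNames(
        100 * length(shared) / pmax(totals, 1L), labels)
    )
  })
  structure(out, labels = labels, class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  for (dir in names(x)) {
    cat(dir, ": shared = ", x[[dir]]$shared,
        "; exclusive = ", paste(x[[dir]]$exclusive, collapse = "/"),
        "; % of directional lists = ",
        paste(sprintf("%.1f", x[[dir]]$pct_of_directional), collapse = "/"),
        "\n", sep = "")
  }
  invisible(x)
}
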