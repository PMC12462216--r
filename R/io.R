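#' Construct and validate a gene-set collection
#'
#' A gene-set collection is a named list of character vectors (term name ->
#' member genes) with a parallel `descriptions` attribute, mirroring the GMT
#' format. Genes are uppercased, whitespace-stripped and deduplicated.
#'
#' @param terms named list of character vectors; every list must be non-empty.
#' @param descriptions optional character vector, recycled to `length(terms)`.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(terms, descriptions = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) > 0L) {
    stopifnot(!is.null(names(terms)), all(nzchar(names(terms))),
              !anyDuplicated(names(terms)))
  }
  terms <- lapply(terms, function(g) {
    g <- unique(toupper(trimws(as.character(g))))
    g <- g[nzchar(g)]
    if (length(g) == 0L) stop("gene set with no genes")
    g
  })
  if (is.null(descriptions)) descriptions <- rep("", length(terms))
  descriptions <- rep_len(as.character(descriptions), length(terms))
  names(descriptions) <- names(terms)
  structure(terms, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "terms\n")
  if (length(x) > 0L) {
    sz <- lengths(x)
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
  }
  invisible(x)
}

canonical_symbols <- function(x) toupper(trimws(as.character(x)))

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate a gene-by-ROI count matrix
#'
#' @param counts integer matrix with gene rownames and ROI colnames.
#' @return The matrix, invisibly, after validation.
#' @keywords internal
validate_count_matrix <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and ROI colnames")
  }
  if (ncol(counts) < 2L) stop("count matrix needs at least 2 ROIs")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(counts))) stop("duplicate ROI ids")
  if (anyNA(counts)) stop("count matrix contains missing values")
  if (any(counts < 0)) stop("count matrix contains negative entries")
  invisible(counts)
}

#' Read a gene x ROI count matrix from TSV/CSV
#'
#' The first column holds gene symbols; remaining columns are ROI counts.
#' Symbols are uppercased and whitespace-stripped; duplicate symbols are
#' collapsed by summation with a warning. Non-integer or negative entries are
#' a hard error naming the offending cell.
#'
#' @param path file path; delimiter is sniffed from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return integer matrix, genes x ROIs.
#' @export
read_count_matrix <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed count file: ", path)
  genes <- canonical_symbols(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count columns in ", path)
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at gene '%s', ROI '%s' in %s",
                 genes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing duplicated gene symbols by summation: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    m <- rowsum(m, group = genes, reorder = FALSE)
    genes <- rownames(m)
  } else {
    rownames(m) <- genes
  }
  storage.mode(m) <- "integer"
  validate_count_matrix(m)
  m
}

#' Write a count matrix as TSV (gene column + one column per ROI)
#' @param counts integer matrix, genes x ROIs.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sniff_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

roi_meta_columns <- c("roi_id", "subject_id", "group", "quadrant",
                      "slide_id", "nuclei_count")

#' Validate ROI metadata against a count matrix
#'
#' @param meta data frame with columns `roi_id`, `subject_id`, `group`,
#'   `quadrant`, `slide_id`, `nuclei_count`.
#' @param counts optional count matrix; every ROI column must have a
#'   metadata row.
#' @param groups,quadrants closed label vocabularies to validate against;
#'   `NULL` skips the vocabulary check (custom designs).
#' @return `meta`, invisibly.
#' @export
validate_roi_metadata <- function(meta, counts = NULL,
                                  groups = c("HC", "PD", "MSAP"),
                                  quadrants = c("DM", "DL", "VM", "VL")) {
  missing_cols <- setdiff(roi_meta_columns, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$roi_id)) stop("duplicate roi_id in metadata")
  if (anyNA(meta$nuclei_count) || any(meta$nuclei_count < 0)) {
    stop("nuclei_count must be a nonnegative integer")
  }
  if (!is.null(groups) && !all(meta$group %in% groups)) {
    stop("group labels outside vocabulary {",
         paste(groups, collapse = ", "), "}")
  }
  if (!is.null(quadrants) && !all(meta$quadrant %in% quadrants)) {
    stop("quadrant labels outside vocabulary {",
         paste(quadrants, collapse = ", "), "}")
  }
  if (!is.null(counts)) {
    missing_rois <- setdiff(colnames(counts), meta$roi_id)
    if (length(missing_rois) > 0L) {
      stop("ROIs without metadata: ",
           paste(utils::head(missing_rois, 5L), collapse = ", "))
    }
  }
  invisible(meta)
}

#' Read ROI metadata from CSV
#' @inheritParams validate_roi_metadata
#' @param path CSV path.
#' @return data frame with the canonical metadata columns.
#' @export
read_roi_metadata <- function(path, groups = c("HC", "PD", "MSAP"),
                              quadrants = c("DM", "DL", "VM", "VL")) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_roi_metadata(meta, groups = groups, quadrants = quadrants)
  meta
}

#' Write ROI metadata as CSV
#' @param meta metadata data frame.
#' @param path output path.
#' @export
write_roi_metadata <- function(meta, path) {
  validate_roi_metadata(meta, groups = NULL, quadrants = NULL)
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' uppercased and deduplicated within a term. A line with fewer than three
#' fields is an error reporting the line number; an empty file yields an
#' empty collection with a warning.
#'
#' @param path GMT path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields in ", path)
  }
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(terms,
                      descriptions = vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected PPI network from a 2+ column edge list
#'
#' Extra columns are ignored. Self-loops are dropped with a warning and
#' duplicate (including reversed) edges collapsed; symbols are uppercased.
#'
#' @param path whitespace/tab-delimited edge-list path.
#' @return An undirected simple named `igraph` graph.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          fill = TRUE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no edges in ", path)
  a <- canonical_symbols(df[[1L]])
  b <- canonical_symbols(df[[2L]])
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  loops <- a == b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)")
    a <- a[!loops]; b <- b[!loops]
  }
  if (length(a) < 1L) stop("fewer than 1 valid edge in ", path)
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  igraph::simplify(g)
}

#' Write a network as a 2-column TSV edge list
#' @param network an `igraph` graph with named vertices.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a differential-expression result table as TSV
#' @param de a data frame as returned by [nb_wald_test()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table written by [write_de_table()]
#' @param path TSV path.
#' @return data frame.
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
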