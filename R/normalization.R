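#' Filter ROIs by nuclei count
#'
#' Keeps only ROIs whose nuclei count strictly exceeds `min_nuclei`
#' (default 90, the segment QC used for substantia nigra ROI selection).
#' Genes are never filtered.
#'
#' @param counts gene x ROI integer matrix.
#' @param meta ROI metadata covering every column of `counts`.
#' @param min_nuclei retention threshold; an ROI is kept iff
#'   `nuclei_count > min_nuclei`.
#' @return list with filtered `counts` and `meta`.
#' @export
filter_rois <- function(counts, meta, min_nuclei = 90) {
  validate_count_matrix(counts)
  validate_roi_metadata(meta, counts, groups = NULL, quadrants = NULL)
  keep_ids <- meta$roi_id[meta$nuclei_count > min_nuclei]
  keep <- colnames(counts) %in% keep_ids
  if (!any(keep)) stop("all ROIs removed by the nuclei filter")
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[match(colnames(counts), meta$roi_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, meta = meta)
}

upper_quartile_nonzero <- function(x) {
  nz <- x[x > 0]
  if (length(nz) == 0L) return(0)
  as.numeric(quantile(nz, 0.75, names = FALSE))
}

median_nonzero <- function(x) {
  nz <- x[x > 0]
  if (length(nz) == 0L) return(0)
  as.numeric(median(nz))
}

geomean <- function(x) exp(mean(log(x)))

#' Between-lane normalization of ROI count columns
#'
#' Brings ROI columns onto a common scale before control-gene factor
#' analysis. Three modes:
#' \describe{
#'   \item{upper}{each column is scaled so its upper quartile of nonzero
#'     counts equals the geometric mean of per-column upper quartiles
#'     (idempotent).}
#'   \item{median}{as `upper` with nonzero medians.}
#'   \item{full}{full-quantile normalization: each column's sorted values
#'     are replaced by the row-wise mean of the sorted columns, then put back
#'     in the original order; ties receive the mean over their tied
#'     positions.}
#' }
#'
#' @param counts gene x ROI matrix of nonnegative counts.
#' @param which normalization mode.
#' @return An object of class `"normalized_matrix"`: list with `values`
#'   (same shape as `counts`), `method`, and `scale_factors` (per-ROI
#'   multipliers; `NA` for full-quantile).
#' @export
between_lane_normalize <- function(counts,
                                   which = c("upper", "full", "median")) {
  which <- match.arg(which)
  validate_count_matrix(counts)
  values <- switch(which,
    upper = ,
    median = {
      stat <- if (which == "upper") upper_quartile_nonzero else median_nonzero
      q <- apply(counts, 2, stat)
      if (any(q <= 0)) {
        stop("zero ", if (which == "upper") "upper quartile" else "median",
             " in ROI ", colnames(counts)[which(q <= 0)[1L]])
      }
      sf <- geomean(q) / q
      out <- sweep(counts, 2, sf, `*`)
      attr(out, "scale_factors") <- sf
      out
    },
    full = {
      sorted <- apply(counts, 2, sort)
      target <- rowMeans(sorted)
      out <- counts
      for (j in seq_len(ncol(counts))) {
        r <- rank(counts[, j], ties.method = "average")
        lo <- floor(r); hi <- ceiling(r)
        out[, j] <- (target[lo] + target[hi]) / 2
      }
      attr(out, "scale_factors") <- rep(NA_real_, ncol(counts))
      out
    }
  )
  sf <- attr(values, "scale_factors")
  attr(values, "scale_factors") <- NULL
  structure(
    list(values = values, method = which,
         scale_factors = stats::setNames(sf, colnames(counts))),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$method, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " ROIs\n", sep = "")
  invisible(x)
}

#' Select empirical control genes from a first-pass group test
#'
#' Runs a first-pass negative-binomial group differential-expression test
#' (joint Wald across all group coefficients when more than two groups are
#' present) and returns the `n_controls` genes that are least associated with
#' group (largest first-pass p-values) among genes with above-median mean
#' expression — the usual "empirical control" convention for RUV.
#'
#' @param counts gene x ROI matrix.
#' @param meta ROI metadata (its `group` column drives the first-pass test).
#' @param n_controls number of controls requested; 0 returns an empty list
#'   (downstream `k` is then forced to 0).
#' @return character vector of control gene symbols.
#' @export
select_empirical_controls <- function(counts, meta, n_controls) {
  validate_count_matrix(counts)
  if (n_controls >= nrow(counts)) {
    stop("n_controls must be smaller than the number of genes")
  }
  if (n_controls == 0L) return(character(0))
  p <- first_pass_group_p(counts, factor(meta$group))
  sf <- size_factors(counts)
  base_mean <- rowMeans(sweep(counts, 2, sf, `/`))
  eligible <- base_mean > median(base_mean)
  ord <- order(ifelse(eligible, p, -Inf), decreasing = TRUE)
  candidates <- ord[eligible[ord]]
  if (length(candidates) < n_controls) {
    warning("fewer above-median-expression genes than requested controls; ",
            "padding with lower-expression genes")
    candidates <- ord
  }
  rownames(counts)[sort(candidates[seq_len(n_controls)])]
}

#' Estimate unwanted-variation factors from control genes (RUVg-style)
#'
#' Factor analysis of the control-gene log expression: the ROI x control
#' matrix of `log(norm + 1)` values is centered per control gene and its
#' first `k` left singular directions in ROI space are returned as
#' mean-centered loading columns. These loadings are meant to enter the
#' differential-expression design as covariates, not to "correct" counts.
#'
#' @param norm a `"normalized_matrix"` (or a plain gene x ROI matrix).
#' @param controls character vector of control gene symbols.
#' @param k number of factors; `k = 0` returns a 0-column matrix.
#' @return ROI x k numeric matrix of mean-centered loadings.
#' @export
estimate_ruv_factors <- function(norm, controls, k = 1L) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  stopifnot(is.matrix(values))
  n_rois <- ncol(values)
  loadings <- matrix(0, n_rois, 0, dimnames = list(colnames(values), NULL))
  if (k == 0L) return(loadings)
  controls <- intersect(controls, rownames(values))
  if (length(controls) == 0L) stop("no control genes found in the matrix")
  if (k > min(length(controls), n_rois - 1L)) {
    stop("k exceeds the feasible rank min(|controls|, n_rois - 1)")
  }
  z <- t(log(values[controls, , drop = FALSE] + 1))  # ROI x controls
  z <- scale(z, center = TRUE, scale = FALSE)        # remove gene baselines
  sv <- svd(z, nu = k, nv = 0)
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  # flat directions (e.g. constant controls) carry no variation
  flat <- sv$d[seq_len(k)] < max(sv$d[1], .Machine$double.eps) * 1e-10
  loadings[, flat] <- 0
  loadings <- scale(loadings, center = TRUE, scale = FALSE)
  dimnames(loadings) <- list(colnames(values), paste0("W", seq_len(k)))
  attr(loadings, "scaled:center") <- NULL
  loadings
}
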