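#' Simulation configuration for GeoMx-style ROI profiling
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the design of a six-donor substantia nigra study: three
#' diagnostic groups (healthy control, Parkinson disease, Parkinsonian-type
#' multiple system atrophy), two subjects per group, one slide per subject
#' and 12 regions of interest (ROIs) per slide, each ROI labelled with one of
#' four anatomical quadrants (dorsomedial, dorsolateral, ventromedial,
#' ventrolateral; three ROIs per quadrant).
#'
#' @param n_genes number of genes (targets) to simulate.
#' @param n_subjects_per_group subjects (= slides) per diagnostic group.
#' @param rois_per_subject ROIs selected per subject; quadrants are assigned
#'   cyclically so a multiple of `length(quadrants)` gives a balanced design.
#' @param groups character vector of group labels; the first is the reference.
#' @param quadrants character vector of quadrant labels.
#' @param frac_de fraction of genes carrying a planted group effect.
#' @param effect_log2fc magnitude of planted log2 fold changes (sign is
#'   randomised per gene).
#' @param nb_dispersion negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`; per-gene dispersions are drawn log-normally
#'   around this value (sdlog 0.3). Zero gives Poisson counts.
#' @param libsize_sigma sdlog of the log-normal per-ROI library-size factor.
#' @param n_unwanted_factors number of slide-correlated unwanted-variation
#'   factors.
#' @param unwanted_sigma standard deviation of per-gene loadings on the
#'   unwanted factors (on the log2 scale); zero disables unwanted variation.
#' @param n_control_genes number of ground-truth control genes (a subset of
#'   the non-DE genes, still exposed to unwanted variation).
#' @param seed integer seed; the whole dataset is deterministic given it.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [generate_dataset()]
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_subjects_per_group = 2L,
                              rois_per_subject = 12L,
                              groups = c("HC", "PD", "MSAP"),
                              quadrants = c("DM", "DL", "VM", "VL"),
                              frac_de = 0.1,
                              effect_log2fc = 2,
                              nb_dispersion = 0.1,
                              libsize_sigma = 0.25,
                              n_unwanted_factors = 1L,
                              unwanted_sigma = 0.5,
                              n_control_genes = 200L,
                              seed = 1L) {
  stopifnot(
    length(n_genes) == 1L, n_genes >= 1,
    length(n_subjects_per_group) == 1L, n_subjects_per_group >= 1,
    length(rois_per_subject) == 1L, rois_per_subject >= 1,
    is.character(groups), length(groups) >= 1L, !anyDuplicated(groups),
    is.character(quadrants), length(quadrants) >= 1L, !anyDuplicated(quadrants),
    frac_de >= 0, frac_de <= 1,
    nb_dispersion >= 0,
    libsize_sigma >= 0,
    n_unwanted_factors >= 0,
    unwanted_sigma >= 0,
    n_control_genes >= 0,
    length(seed) == 1L, is.finite(seed)
  )
  if (n_genes < 2L * n_control_genes) {
    stop("n_genes must be at least twice n_control_genes so that controls ",
         "can be a subset of the non-DE genes")
  }
  if (frac_de > 0 && length(groups) < 2L) {
    stop("planted differential expression requires at least two groups")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_subjects_per_group = as.integer(n_subjects_per_group),
      rois_per_subject = as.integer(rois_per_subject),
      groups = groups,
      quadrants = quadrants,
      frac_de = frac_de,
      effect_log2fc = effect_log2fc,
      nb_dispersion = nb_dispersion,
      libsize_sigma = libsize_sigma,
      n_unwanted_factors = as.integer(n_unwanted_factors),
      unwanted_sigma = unwanted_sigma,
      n_control_genes = as.integer(n_control_genes),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a synthetic GeoMx-style dataset with known ground truth
#'
#' Draws a gene-by-ROI negative-binomial count matrix with per-ROI
#' library-size factors, log-normal baseline expression spanning roughly
#' three orders of magnitude, planted group log2 fold changes on a random
#' subset of genes, and slide-correlated unwanted-variation factors acting on
#' all genes (including the designated control genes). The expected count is
#'
#'   `mu_gj = s_j * q_g * 2^(x_gj * beta_g + sum_f w_jf * a_gf)`
#'
#' where `s_j` is the ROI library-size factor, `q_g` the baseline, `x_gj` the
#' indicator that ROI `j` belongs to gene `g`'s planted contrast group,
#' and `w`/`a` the unwanted-factor loadings.
#'
#' @param config a [simulation_config()].
#' @return A list with elements:
#' \describe{
#'   \item{counts}{integer matrix, genes x ROIs, with dimnames.}
#'   \item{meta}{data frame with `roi_id`, `subject_id`, `group`, `quadrant`,
#'     `slide_id`, `nuclei_count` (uniform in 50..300).}
#'   \item{truth}{list: `de_genes` (data frame `gene`, `contrast`,
#'     `log2fc`), `unwanted_loadings` (ROI x factor matrix),
#'     `control_genes` (character).}
#' }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  subjects <- as.vector(t(outer(config$groups,
                                seq_len(config$n_subjects_per_group),
                                function(g, i) paste0(g, "_S", i))))
  subj_group <- rep(config$groups, each = config$n_subjects_per_group)
  n_rois <- length(subjects) * config$rois_per_subject

  roi_subject <- rep(subjects, each = config$rois_per_subject)
  roi_group <- rep(subj_group, each = config$rois_per_subject)
  roi_id <- paste0(roi_subject, "_R",
                   sprintf("%02d", rep(seq_len(config$rois_per_subject),
                                       times = length(subjects))))
  # balanced cyclic quadrant assignment within each subject
  quadrant <- rep(rep_len(config$quadrants, config$rois_per_subject),
                  times = length(subjects))
  meta <- data.frame(
    roi_id = roi_id,
    subject_id = roi_subject,
    group = roi_group,
    quadrant = quadrant,
    slide_id = roi_subject,        # one slide per subject
    nuclei_count = sample(50:300, n_rois, replace = TRUE),
    stringsAsFactors = FALSE
  )

  q_g <- rlnorm(config$n_genes, meanlog = log(50), sdlog = 1.5)
  disp_g <- if (config$nb_dispersion > 0) {
    rlnorm(config$n_genes, meanlog = log(config$nb_dispersion), sdlog = 0.3)
  } else {
    rep(0, config$n_genes)
  }
  s_j <- if (config$libsize_sigma > 0) {
    rlnorm(n_rois, 0, config$libsize_sigma)
  } else {
    rep(1, n_rois)
  }

  n_de <- as.integer(round(config$frac_de * config$n_genes))
  de_idx <- if (n_de > 0) sort(sample.int(config$n_genes, n_de)) else integer(0)
  de_contrast <- if (n_de > 0) {
    sample(config$groups[-1], n_de, replace = TRUE)
  } else {
    character(0)
  }
  de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  de_lfc <- de_sign * config$effect_log2fc

  non_de <- setdiff(seq_len(config$n_genes), de_idx)
  control_idx <- if (config$n_control_genes > 0) {
    sort(sample(non_de, config$n_control_genes))
  } else {
    integer(0)
  }

  # slide-correlated unwanted factors: shared subject loading plus ROI noise
  k <- config$n_unwanted_factors
  W <- matrix(0, n_rois, k,
              dimnames = list(roi_id, if (k > 0) paste0("W", seq_len(k))))
  A <- matrix(0, config$n_genes, max(k, 1L))
  if (k > 0 && config$unwanted_sigma > 0) {
    for (f in seq_len(k)) {
      u <- rnorm(length(subjects))
      w <- u[match(roi_subject, subjects)] + rnorm(n_rois, sd = 0.3)
      W[, f] <- as.vector(scale(w))
    }
    A <- matrix(rnorm(config$n_genes * k, sd = config$unwanted_sigma),
                config$n_genes, k)
  }

  log2mu <- matrix(log2(q_g), config$n_genes, n_rois)
  if (n_de > 0) {
    for (i in seq_along(de_idx)) {
      in_grp <- roi_group == de_contrast[i]
      log2mu[de_idx[i], in_grp] <- log2mu[de_idx[i], in_grp] + de_lfc[i]
    }
  }
  if (k > 0 && config$unwanted_sigma > 0) {
    log2mu <- log2mu + A %*% t(W)
  }
  mu <- sweep(2^log2mu, 2, s_j, `*`)

  size_mat <- matrix(ifelse(disp_g > 0, 1 / disp_g, Inf),
                     config$n_genes, n_rois)
  counts <- matrix(0L, config$n_genes, n_rois,
                   dimnames = list(genes, roi_id))
  pois <- !is.finite(size_mat)
  if (any(pois)) counts[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    counts[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = size_mat[!pois])
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    de_genes = data.frame(
      gene = genes[de_idx],
      contrast = de_contrast,
      log2fc = de_lfc,
      stringsAsFactors = FALSE
    ),
    unwanted_loadings = W,
    control_genes = genes[control_idx]
  )
  list(counts = counts, meta = meta, truth = truth)
}

#' Generate a scale-free synthetic protein-protein interaction network
#'
#' Preferential-attachment (Barabasi-Albert) growth yields a connected,
#' simple, undirected graph with a heavy-tailed degree distribution, standing
#' in for a BioGRID-style PPI network. Node labels are gene symbols.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param edges_per_node edges attached by each incoming node
#'   (1 <= `edges_per_node` <= `n_nodes - 1`).
#' @param seed integer seed.
#' @param genes optional pool of gene symbols to label the nodes; must have
#'   at least `n_nodes` entries. Default labels are `GENE%05d`.
#' @return An undirected, named `igraph` graph with one connected component,
#'   no self-loops and no multi-edges.
#' @export
generate_ppi <- function(n_nodes, edges_per_node, seed = 1L, genes = NULL) {
  stopifnot(n_nodes >= 3, edges_per_node >= 1)
  if (edges_per_node > n_nodes - 1) {
    stop("edges_per_node must be <= n_nodes - 1 for a simple connected graph")
  }
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  g <- igraph::simplify(g)
  labels <- if (is.null(genes)) {
    sprintf("GENE%05d", seq_len(n_nodes))
  } else {
    stopifnot(length(genes) >= n_nodes)
    sample(genes, n_nodes)
  }
  igraph::V(g)$name <- labels
  g
}

#' Generate a synthetic gene-set collection
#'
#' Random gene sets drawn from a gene universe, GMT-writable. Optionally one
#' term (named `PLANTED_TERM`) contains a supplied gene list entirely, so
#' enrichment recovery can be tested against a known answer.
#'
#' @param genes gene universe (non-empty character vector).
#' @param n_sets number of terms.
#' @param set_size_range length-2 integer range of set sizes.
#' @param planted_set optional character vector fully contained in the first
#'   term.
#' @param seed integer seed.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(genes, n_sets = 50L,
                               set_size_range = c(10L, 50L),
                               planted_set = NULL, seed = 1L) {
  if (length(genes) == 0L) stop("gene universe is empty")
  stopifnot(length(set_size_range) == 2L,
            set_size_range[1] >= 1,
            set_size_range[2] <= length(genes),
            set_size_range[1] <= set_size_range[2])
  set.seed(seed)
  sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                  n_sets, replace = TRUE)
  terms <- lapply(sizes, function(sz) sample(genes, sz))
  names(terms) <- sprintf("TERM_%03d", seq_len(n_sets))
  if (!is.null(planted_set)) {
    planted_set <- unique(toupper(trimws(planted_set)))
    stopifnot(length(planted_set) >= 1)
    terms[[1L]] <- planted_set
    names(terms)[1L] <- "PLANTED_TERM"
  }
  gene_set_collection(terms,
                      descriptions = rep("synthetic gene set", n_sets))
}
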