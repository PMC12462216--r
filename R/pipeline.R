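#' Run one group contrast end-to-end
#'
#' Executes the full ROI analysis for a single `test` vs `reference`
#' contrast: nuclei-count ROI filter, between-lane normalization, empirical
#' control selection, unwanted-variation factor estimation, negative-
#' binomial Wald differential expression (with the RUV loadings as design
#' covariates), per-direction over-representation analysis, and random-walk
#' network propagation with betweenness-based key-gene selection. All
#' artifacts are written as plain-text tables under `out_dir` together with
#' a JSON run manifest.
#'
#' @param counts gene x ROI raw count matrix.
#' @param meta ROI metadata data frame.
#' @param network PPI `igraph` graph (named vertices).
#' @param gene_sets a [gene_set_collection()] (may be `NULL` to skip
#'   enrichment).
#' @param contrast length-2 character `c(test, reference)`.
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param min_nuclei ROI retention threshold (strictly greater than).
#' @param norm_method between-lane mode passed to
#'   [between_lane_normalize()].
#' @param n_controls empirical control genes for RUV; 0 disables RUV.
#' @param ruv_k number of unwanted-variation factors.
#' @param alpha significance level on adjusted p.
#' @param r,prob_quantile,bc_quantile propagation parameters, see
#'   [propagate_degs()].
#' @param stratum optional quadrant label restricting the contrast.
#' @return list with `de`, `enrichment` (list `up`/`down`, possibly `NULL`),
#'   `propagation` (data frame or `NULL` when no DEG maps), `controls`,
#'   `ruv` (ROI x k loadings), `manifest`.
#' @export
run_contrast <- function(counts, meta, network = NULL, gene_sets = NULL,
                         contrast, out_dir = NULL, min_nuclei = 90,
                         norm_method = "upper", n_controls = 200L,
                         ruv_k = 1L, alpha = 0.05, r = 0.7,
                         prob_quantile = 0.90, bc_quantile = 0.90,
                         stratum = NULL) {
  t0 <- proc.time()[["elapsed"]]
  flt <- filter_rois(counts, meta, min_nuclei = min_nuclei)
  counts <- flt$counts; meta <- flt$meta

  norm <- between_lane_normalize(counts, which = norm_method)
  if (n_controls > 0L && ruv_k > 0L) {
    controls <- select_empirical_controls(counts, meta, n_controls)
    ruv <- estimate_ruv_factors(norm, controls, k = ruv_k)
  } else {
    controls <- character(0)
    ruv <- matrix(0, ncol(counts), 0,
                  dimnames = list(colnames(counts), NULL))
  }

  de <- nb_wald_test(counts, meta, contrast = contrast,
                     covariates = if (ncol(ruv) > 0) ruv else NULL,
                     stratum = stratum, alpha = alpha)

  up <- de$gene[de$direction == "up"]
  down <- de$gene[de$direction == "down"]

  enr <- NULL
  if (!is.null(gene_sets)) {
    universe <- rownames(counts)
    enr <- list(up = NULL, down = NULL)
    if (length(up) > 0L) {
      enr$up <- fisher_enrich(up, universe, gene_sets)
    } else {
      message("no upregulated DEGs; enrichment skipped for 'up'")
    }
    if (length(down) > 0L) {
      enr$down <- fisher_enrich(down, universe, gene_sets)
    } else {
      message("no downregulated DEGs; enrichment skipped for 'down'")
    }
  }

  prop <- NULL
  if (!is.null(network) && (length(up) + length(down)) > 0L) {
    prop <- tryCatch(
      propagate_degs(de, network, alpha = alpha, r = r,
                     prob_quantile = prob_quantile,
                     bc_quantile = bc_quantile),
      error = function(e) {
        message("network propagation skipped: ", conditionMessage(e))
        NULL
      }
    )
  } else if (!is.null(network)) {
    message("no significant DEGs; network propagation skipped")
  }

  manifest <- list(
    contrast = paste(contrast, collapse = "_vs_"),
    stratum = if (is.null(stratum)) NA_character_ else stratum,
    package_version = as.character(utils::packageVersion("nigraspace")),
    parameters = list(min_nuclei = min_nuclei, norm_method = norm_method,
                      n_controls = n_controls, ruv_k = ruv_k, alpha = alpha,
                      r = r, prob_quantile = prob_quantile,
                      bc_quantile = bc_quantile),
    rows = list(
      rois_retained = ncol(counts),
      genes = nrow(counts),
      degs_up = length(up),
      degs_down = length(down),
      key_genes = if (is.null(prop)) 0L else sum(prop$key)
    ),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )

  result <- list(de = de, enrichment = enr, propagation = prop,
                 controls = controls, ruv = ruv, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- manifest$contrast
    if (!is.null(stratum)) tag <- paste0(tag, "_", stratum)
    write_de_table(de, file.path(out_dir, paste0("de_", tag, ".tsv")))
    if (!is.null(prop)) {
      utils::write.table(prop, file.path(out_dir,
                                         paste0("netprop_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (dir in c("up", "down")) {
      e <- enr[[dir]]
      if (!is.null(e)) {
        flat <- e
        flat$overlap_genes <- vapply(e$overlap_genes, paste, "",
                                     collapse = ",")
        utils::write.table(flat,
                           file.path(out_dir,
                                     paste0("enrich_", dir, "_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_manifest(manifest,
                   file.path(out_dir, paste0("manifest_", tag, ".json")))
  }
  result
}

# atomic JSON manifest write
write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Quadrant-stratified differential expression
#'
#' Runs the contrast independently within each quadrant's ROIs, with
#' Benjamini-Hochberg adjustment per stratum (quadrant analyses are reported
#' as separate comparisons, not pooled). Strata with fewer than 2 ROIs in
#' either group are skipped with a warning.
#'
#' @inheritParams run_contrast
#' @param quadrants quadrant labels to analyse (default: those present in
#'   the metadata).
#' @return named list of DE result tables, one per retained quadrant.
#' @export
run_quadrants <- function(counts, meta, contrast, quadrants = NULL,
                          min_nuclei = 90, n_controls = 200L, ruv_k = 1L,
                          alpha = 0.05, out_dir = NULL) {
  flt <- filter_rois(counts, meta, min_nuclei = min_nuclei)
  counts <- flt$counts; meta <- flt$meta
  if (is.null(quadrants)) quadrants <- unique(meta$quadrant)

  norm <- between_lane_normalize(counts)
  if (n_controls > 0L && ruv_k > 0L) {
    controls <- select_empirical_controls(counts, meta, n_controls)
    ruv <- estimate_ruv_factors(norm, controls, k = ruv_k)
  } else {
    ruv <- NULL
  }

  out <- list()
  for (q in quadrants) {
    in_q <- meta$quadrant == q
    n_test <- sum(meta$group[in_q] == contrast[1L])
    n_ref <- sum(meta$group[in_q] == contrast[2L])
    if (!any(in_q) || n_test < 2L || n_ref < 2L) {
      warning("quadrant '", q, "' skipped: ", n_test, " test / ", n_ref,
              " reference ROIs")
      next
    }
    out[[q]] <- nb_wald_test(counts, meta, contrast = contrast,
                             covariates = ruv, stratum = q, alpha = alpha)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_de_table(out[[q]],
                     file.path(out_dir,
                               paste0("de_", paste(contrast, collapse = "_vs_"),
                                      "_", q, ".tsv")))
    }
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Reads every input from disk, runs all configured contrasts (and the
#' quadrant-stratified analyses when `quadrant_mode` is on), computes the
#' DEG-overlap Venn summary across contrasts, and writes a run manifest
#' with input checksums. The configuration may be a YAML file path or an
#' equivalent named list with entries:
#'
#' ```yaml
#' counts: counts.tsv
#' meta: meta.csv
#' network: ppi.tsv          # optional
#' gene_sets: sets.gmt       # optional
#' contrasts:
#'   - [MSAP, HC]
#'   - [PD, HC]
#' quadrant_mode: true
#' out_dir: results
#' params: {min_nuclei: 90, n_controls: 200, ruv_k: 1, alpha: 0.05, r: 0.7}
#' ```
#'
#' @param config YAML path or named list.
#' @return list with one element per contrast (each a [run_contrast()]
#'   result), plus `quadrants` (when enabled), `venn` (when >= 2 contrasts)
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$counts), !is.null(config$meta),
            !is.null(config$contrasts))
  paths <- c(counts = config$counts, meta = config$meta,
             network = config$network, gene_sets = config$gene_sets)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L) {
    stop("missing input file(s): ", paste(missing_paths, collapse = ", "))
  }

  counts <- read_count_matrix(config$counts)
  meta <- read_roi_metadata(config$meta, groups = NULL, quadrants = NULL)
  validate_roi_metadata(meta, counts, groups = NULL, quadrants = NULL)
  network <- if (!is.null(config$network)) read_edge_list(config$network)
  gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)

  prm <- config$params
  if (is.null(prm)) prm <- list()
  getp <- function(name, default) if (is.null(prm[[name]])) default else prm[[name]]

  out_dir <- config$out_dir
  results <- list(contrasts = list())
  for (ct in config$contrasts) {
    ct <- as.character(ct)
    tag <- paste(ct, collapse = "_vs_")
    results$contrasts[[tag]] <- run_contrast(
      counts, meta, network, gene_sets, contrast = ct, out_dir = out_dir,
      min_nuclei = getp("min_nuclei", 90),
      norm_method = getp("norm_method", "upper"),
      n_controls = getp("n_controls", 200L),
      ruv_k = getp("ruv_k", 1L),
      alpha = getp("alpha", 0.05),
      r = getp("r", 0.7),
      prob_quantile = getp("prob_quantile", 0.90),
      bc_quantile = getp("bc_quantile", 0.90)
    )
    if (isTRUE(config$quadrant_mode)) {
      results$quadrants[[tag]] <- run_quadrants(
        counts, meta, contrast = ct,
        min_nuclei = getp("min_nuclei", 90),
        n_controls = getp("n_controls", 200L),
        ruv_k = getp("ruv_k", 1L),
        alpha = getp("alpha", 0.05),
        out_dir = out_dir
      )
    }
  }

  if (length(results$contrasts) >= 2L) {
    venn_in <- lapply(results$contrasts, function(res) {
      list(up = res$de$gene[res$de$direction == "up"],
           down = res$de$gene[res$de$direction == "down"])
    })
    results$venn <- venn_overlap(venn_in)
    if (!is.null(out_dir)) {
      write_manifest(unclass(results$venn), file.path(out_dir, "venn.json"))
    }
  }

  results$manifest <- list(
    package_version = as.character(utils::packageVersion("nigraspace")),
    config = config,
    input_md5 = as.list(tools::md5sum(paths)),
    contrasts = names(results$contrasts)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(results$manifest, file.path(out_dir, "run_manifest.json"))
  }
  results
}
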