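#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with the defaults used
#' throughout: QC keeps cells with more than `min_genes` detected genes,
#' below `max_mito` mitochondrial and `max_ribo` ribosomal UMI fraction;
#' scoring uses `n_bins` expression bins and `n_ctrl` control genes per
#' target gene; granulation searches for a clustering resolution giving a
#' median granule size inside `[lower_median, upper_median]` and reassigns
#' granules smaller than `min_granule`; thresholds use the Gaussian
#' `q`-quantile.
#'
#' @param min_genes minimum detected genes per cell (strictly more required).
#' @param max_mito maximum mitochondrial UMI fraction (strictly below).
#' @param max_ribo maximum ribosomal UMI fraction (strictly below).
#' @param mito_regex,ribo_regex case-insensitive regexes identifying
#'   mitochondrial and ribosomal gene symbols; defaults fit human symbols.
#' @param n_hvg number of highly variable genes (clamped to the gene count).
#' @param n_pcs number of principal components.
#' @param knn_k neighbors for the kNN/SNN graph (the cell itself included).
#' @param snn_prune SNN Jaccard weights below this are dropped.
#' @param umap_n_neighbors,umap_min_dist UMAP parameters.
#' @param lower_median,upper_median target interval for the median granule
#'   size during the resolution search, in cells.
#' @param min_granule granules below this size are dissolved and their cells
#'   reassigned to the nearest retained granule centroid in 3-D UMAP space.
#' @param max_iter cap on clustering calls during the resolution search.
#' @param q quantile of the fitted Gaussian used as the score threshold.
#' @param n_bins expression bins for control-gene matching.
#' @param n_ctrl control genes sampled per target gene.
#' @param min_set_size minimum detected genes a set must retain to be scored.
#' @param seed global random seed; per-stage seeds are derived from it.
#' @param manual_thresholds named numeric vector of per-score threshold
#'   overrides replacing the automatic fit (recorded as `source = "manual"`).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(min_genes = 500, max_mito = 0.20, max_ribo = 0.30,
                       mito_regex = "^MT-", ribo_regex = "^RP[LS]",
                       n_hvg = 2000, n_pcs = 50, knn_k = 20,
                       snn_prune = 1 / 15,
                       umap_n_neighbors = 30, umap_min_dist = 0.3,
                       lower_median = 100, upper_median = 200,
                       min_granule = 30, max_iter = 30,
                       q = 0.99, n_bins = 25, n_ctrl = 100,
                       min_set_size = 5, seed = 1,
                       manual_thresholds = NULL) {
  cfg <- list(min_genes = min_genes, max_mito = max_mito,
              max_ribo = max_ribo, mito_regex = mito_regex,
              ribo_regex = ribo_regex, n_hvg = n_hvg, n_pcs = n_pcs,
              knn_k = knn_k, snn_prune = snn_prune,
              umap_n_neighbors = umap_n_neighbors,
              umap_min_dist = umap_min_dist,
              lower_median = lower_median, upper_median = upper_median,
              min_granule = min_granule, max_iter = max_iter, q = q,
              n_bins = n_bins, n_ctrl = n_ctrl,
              min_set_size = min_set_size, seed = seed,
              manual_thresholds = manual_thresholds)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$lower_median < cfg$upper_median,
            cfg$q > 0, cfg$q < 1,
            cfg$min_granule >= 2,
            cfg$n_bins >= 1, cfg$n_ctrl >= 1,
            cfg$n_hvg >= 1, cfg$n_pcs >= 1, cfg$knn_k >= 2)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take the
#' [run_config()] defaults. `manual_thresholds` may be given as a mapping of
#' score name to cutoff.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("read_config: file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  defaults <- run_config()
  known <- names(unclass(defaults))
  extra <- setdiff(names(vals), c(known, "gene_sets", "input", "out_dir"))
  if (length(extra))
    stop("read_config: unknown keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  cfg <- unclass(defaults)
  for (k in intersect(names(vals), known)) cfg[[k]] <- vals[[k]]
  if (!is.null(cfg$manual_thresholds))
    cfg$manual_thresholds <- unlist(cfg$manual_thresholds)
  cfg <- validate_config(cfg)
  attr(cfg, "gene_sets") <- vals$gene_sets
  attr(cfg, "input") <- vals$input
  attr(cfg, "out_dir") <- vals$out_dir
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- unclass(x)
  flat$manual_thresholds <- NULL
  for (k in names(flat)) cat(sprintf("  %-18s %s\n", k,
                                     paste(format(unlist(flat[[k]])),
                                           collapse = " ")))
  if (!is.null(x$manual_thresholds))
    cat("  manual thresholds:",
        paste(names(x$manual_thresholds), x$manual_thresholds,
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Derive an independent, reproducible seed for a named pipeline stage from
# the single user-facing seed. Stays below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
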