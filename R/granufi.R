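#' Fit the granule-based stress-filtering model
#'
#' Runs the full pipeline on a raw count matrix: QC filtering, CP10K/log1p
#' normalization, variable-gene selection, PCA/SNN/3-D UMAP, gene-set
#' scoring with binned control genes, resolution-searched granulation with
#' small-granule reassignment, granule-score aggregation, automatic
#' threshold fitting and stress calling.
#'
#' @param counts cells x genes count matrix (see [count_matrix()]) or a path
#'   to a 10x-convention MTX directory.
#' @param gene_sets named list of [gene_set()] objects carrying their
#'   directions, or a path to a GMT file (all sets positive unless
#'   `negative` names some of them).
#' @param config a [run_config()].
#' @param negative character vector of set names to treat as negative
#'   lineage filters (convenience when `gene_sets` is a GMT path).
#' @param mode `"granular"` (default) thresholds granule-averaged scores;
#'   `"single_cell"` thresholds raw per-cell scores with the same logic.
#' @param verbose print stage progress.
#' @return an object of class `granufi` holding the QC'd counts (`counts`),
#'   normalized matrix (`norm`), `hvg`, `embeddings`, `score_table`,
#'   `partition`, `granule_scores`, threshold `fits`, `calls`, `config` and
#'   the QC report. Methods: [print.granufi()], [summary.granufi()],
#'   [coef.granufi()], [predict.granufi()], [plot.granufi()].
#' @export
granufi <- function(counts, gene_sets, config = run_config(),
                    negative = NULL, mode = c("granular", "single_cell"),
                    verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message("granufi: ", ...)
  if (is.character(counts) && length(counts) == 1)
    counts <- read_10x_mtx(counts)
  if (is.character(gene_sets) && length(gene_sets) == 1)
    gene_sets <- read_gmt(gene_sets)
  if (!is.null(negative))
    for (s in negative) gene_sets[[s]] <- set_direction(gene_sets[[s]],
                                                        "negative")

  say("QC filtering ", nrow(counts), " cells")
  counts <- qc_filter(counts, min_genes = config$min_genes,
                      max_mito = config$max_mito,
                      max_ribo = config$max_ribo,
                      mito_regex = config$mito_regex,
                      ribo_regex = config$ribo_regex)
  qc_report <- attr(counts, "qc_report")
  say(qc_report$n_kept, " cells pass QC")

  nm <- normalize_counts(counts)
  hvg <- select_hvg(nm, n = min(config$n_hvg, ncol(nm)))
  say("embedding ", length(hvg), " variable genes")
  emb <- embed_cells(nm, hvg, n_pcs = config$n_pcs, knn_k = config$knn_k,
                     snn_prune = config$snn_prune,
                     umap_n_neighbors = config$umap_n_neighbors,
                     umap_min_dist = config$umap_min_dist,
                     seed = config$seed)

  say("scoring ", length(gene_sets), " gene sets")
  st <- score_all(nm, gene_sets, cfg = config)
  directions <- vapply(st$sets, `[[`, "", "direction")

  say("searching clustering resolution")
  p <- auto_resolution(emb$snn, lower_median = config$lower_median,
                       upper_median = config$upper_median,
                       max_iter = config$max_iter,
                       seed = stage_seed(config$seed, "cluster"))
  say("resolution ", format(p$resolution), ": ", length(p$sizes),
      " granules, median size ", stats::median(p$sizes))
  p <- reassign_small(p, emb$umap3, min_granule = config$min_granule)

  gt <- aggregate_scores(st, p)
  if (mode == "granular") {
    fits <- fit_all_thresholds(gt$scores, directions, q = config$q,
                               manual_thresholds = config$manual_thresholds)
    calls <- combine_and_call(gt, fits, p)
  } else {
    calls <- single_cell_call(st, directions, q = config$q,
                              manual_thresholds = config$manual_thresholds)
    fits <- calls$fits
  }
  say(sum(calls$cell_stressed), " / ", length(calls$cell_stressed),
      " cells called stressed")

  structure(list(counts = counts, norm = nm, hvg = hvg, embeddings = emb,
                 score_table = st, partition = p, granule_scores = gt,
                 fits = fits, calls = calls, config = config,
                 qc_report = qc_report, mode = mode),
            class = "granufi")
}

#' @export
print.granufi <- function(x, ...) {
  cat("Granule-based stress filter fit\n")
  cat(sprintf("  cells: %d (of %d after QC)\n", nrow(x$counts),
              x$qc_report$n_input))
  cat(sprintf("  granules: %d (median size %s, resolution %s)\n",
              length(x$partition$sizes),
              format(stats::median(x$partition$sizes)),
              format(x$partition$resolution)))
  cat(sprintf("  stressed: %d cells (%.1f%%), mode %s\n",
              sum(x$calls$cell_stressed),
              100 * mean(x$calls$cell_stressed), x$mode))
  invisible(x)
}

#' Summary of a fitted stress filter
#'
#' @param object a `granufi` fit.
#' @param ... unused.
#' @return the fit, invisibly; prints QC, granulation, per-score threshold
#'   and call statistics.
#' @export
summary.granufi <- function(object, ...) {
  x <- object
  print(x)
  cat("\nQC report:\n")
  r <- x$qc_report
  cat(sprintf("  input %d, kept %d (low genes %d, high mito %d, high ribo %d)\n",
              r$n_input, r$n_kept, r$removed_low_genes, r$removed_high_mito,
              r$removed_high_ribo))
  cat("\nThresholds:\n")
  for (f in x$fits) {
    cat("  "); print(f)
  }
  cat("\nGranule sizes:\n")
  print(summary(as.numeric(x$partition$sizes)))
  invisible(x)
}

#' Fitted score thresholds
#'
#' @param object a `granufi` fit.
#' @param ... unused.
#' @return named numeric vector of per-score thresholds.
#' @export
coef.granufi <- function(object, ...) {
  vapply(object$fits, `[[`, 0, "t")
}

#' Classify new score observations with the fitted thresholds
#'
#' @param object a `granufi` fit.
#' @param newdata a matrix (rows x score columns matching the fitted score
#'   names), a `score_table`, or `NULL` to return the fitted per-cell calls.
#' @param ... unused.
#' @return named logical vector of stress calls.
#' @export
predict.granufi <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$calls$cell_stressed)
  if (inherits(newdata, "score_table")) newdata <- newdata$scores
  calls <- call_from_matrix(newdata, object$fits, mode = "single_cell")
  calls$cell_stressed
}

#' Granule-score histograms with fitted thresholds
#'
#' One histogram per score of the granule-level (or cell-level, in
#' single-cell mode) scores, with the threshold marked; granules above a
#' positive threshold are called stressed unless vetoed by a negative score.
#'
#' @param x a `granufi` fit.
#' @param ... passed to [graphics::hist()].
#' @return the fit, invisibly.
#' @export
plot.granufi <- function(x, ...) {
  mat <- if (x$mode == "granular") x$granule_scores$scores
         else x$score_table$scores
  old <- par(mfrow = c(1, ncol(mat)))
  on.exit(par(old))
  for (s in colnames(mat)) {
    f <- x$fits[[s]]
    hist(mat[, s], breaks = 30, main = sprintf("%s (%s)", s, f$direction),
         xlab = "granule score", ...)
    abline(v = f$t, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Counts with stressed cells removed
#'
#' Convenience wrapper for [filter_cells()] on a fit: returns the QC'd count
#' matrix restricted to non-stressed cells. Downstream embeddings must be
#' recomputed on the filtered matrix.
#'
#' @param fit a `granufi` fit.
#' @return cells x genes sparse count matrix.
#' @export
filtered_counts <- function(fit) {
  stopifnot(inherits(fit, "granufi"))
  filter_cells(fit$counts, fit$calls)
}
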