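#' Quality-control filter on a count matrix
#'
#' Keeps cells with strictly more than `min_genes` detected genes, a
#' mitochondrial UMI fraction strictly below `max_mito` and a ribosomal UMI
#' fraction strictly below `max_ribo`. The three rules are conjunctive, so
#' removal counts do not depend on rule order. Mitochondrial and ribosomal
#' genes are recognized by case-insensitive symbol regexes (human defaults
#' `^MT-` and `^RP[LS]`).
#'
#' @param m cells x genes count matrix.
#' @param min_genes,max_mito,max_ribo thresholds; defaults 500 genes, 20%
#'   mitochondrial, 30% ribosomal.
#' @param mito_regex,ribo_regex symbol patterns (case-insensitive).
#' @return the filtered matrix with an attached `qc_report` attribute: a list
#'   with per-rule removal counts and the kept-cell count.
#' @export
qc_filter <- function(m, min_genes = 500, max_mito = 0.20, max_ribo = 0.30,
                      mito_regex = "^MT-", ribo_regex = "^RP[LS]") {
  check_cells_by_genes(m, "qc_filter")
  genes <- colnames(m)
  totals <- Matrix::rowSums(m)
  n_detected <- Matrix::rowSums(m > 0)
  mito_cols <- grepl(mito_regex, genes, ignore.case = TRUE)
  ribo_cols <- grepl(ribo_regex, genes, ignore.case = TRUE)
  mito_frac <- ribo_frac <- rep(0, nrow(m))
  nz <- totals > 0
  if (any(mito_cols))
    mito_frac[nz] <- Matrix::rowSums(m[, mito_cols, drop = FALSE])[nz] /
      totals[nz]
  if (any(ribo_cols))
    ribo_frac[nz] <- Matrix::rowSums(m[, ribo_cols, drop = FALSE])[nz] /
      totals[nz]

  pass_genes <- n_detected > min_genes
  pass_mito <- mito_frac < max_mito
  pass_ribo <- ribo_frac < max_ribo
  keep <- pass_genes & pass_mito & pass_ribo
  if (!any(keep))
    stop("qc_filter: no cells pass QC (gene-count fail: ",
         sum(!pass_genes), ", mito fail: ", sum(!pass_mito),
         ", ribo fail: ", sum(!pass_ribo), " of ", nrow(m), " cells)",
         call. = FALSE)
  out <- m[keep, , drop = FALSE]
  attr(out, "qc_report") <- list(
    n_input = nrow(m), n_kept = sum(keep),
    removed_low_genes = sum(!pass_genes),
    removed_high_mito = sum(!pass_mito),
    removed_high_ribo = sum(!pass_ribo))
  out
}

#' Library-size normalization (CP10K + log1p)
#'
#' Each cell is scaled to a total of 10,000 counts and log-transformed:
#' `value = log1p(10000 * count / cell_total)`. Cells with zero total counts
#' yield all-zero rows and raise a warning.
#'
#' @param m cells x genes count matrix.
#' @return cells x genes sparse matrix of normalized values.
#' @export
normalize_counts <- function(m) {
  check_cells_by_genes(m, "normalize_counts")
  totals <- Matrix::rowSums(m)
  if (any(totals == 0))
    warning("normalize_counts: ", sum(totals == 0),
            " cell(s) with zero total counts produce all-zero rows")
  scale <- ifelse(totals > 0, 1e4 / totals, 0)
  nm <- Matrix::Diagonal(x = scale) %*% m
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(m)
  as(nm, "CsparseMatrix")
}

#' Select highly variable genes by log variance-to-mean ratio
#'
#' Genes are ranked by the log of the variance-to-mean ratio of their
#' back-transformed (`expm1`) normalized expression, descending; ties are
#' broken by symbol order. Genes with zero mean or zero variance rank last.
#'
#' @param nm normalized matrix from [normalize_counts()].
#' @param n number of genes to return.
#' @return character vector of the `n` top-ranked gene symbols.
#' @export
select_hvg <- function(nm, n = 2000) {
  check_cells_by_genes(nm, "select_hvg")
  if (n <= 0) stop("select_hvg: n must be positive", call. = FALSE)
  if (n > ncol(nm))
    stop("select_hvg: n exceeds gene count", call. = FALSE)
  e <- nm
  e@x <- expm1(e@x)
  mu <- Matrix::colMeans(e)
  # var with the usual n-1 divisor, computed sparsely from first two moments
  ncell <- nrow(e)
  sumsq <- Matrix::colSums(e ^ 2)
  v <- (sumsq - ncell * mu ^ 2) / max(ncell - 1, 1)
  v <- pmax(v, 0)
  lvmr <- ifelse(mu > 0 & v > 0, log(v / mu), -Inf)
  ord <- order(-lvmr, colnames(nm))
  colnames(nm)[ord[seq_len(n)]]
}

#' PCA, kNN/SNN graph and UMAP embeddings
#'
#' The highly variable genes are scaled to zero mean and unit variance,
#' reduced to `n_pcs` principal components (truncated SVD), and a k-nearest
#' neighbor graph (Euclidean, the cell itself included among its neighbors)
#' is built in PC space. The shared-nearest-neighbor graph weights each cell
#' pair by the Jaccard similarity of their neighbor sets, pruning weights
#' below `snn_prune`. A 3-D UMAP (and optionally 2-D) is computed from the
#' PC space; all stochastic steps honor `seed`.
#'
#' @param nm normalized matrix.
#' @param hvg character vector of variable gene symbols.
#' @param n_pcs,knn_k,snn_prune,umap_n_neighbors,umap_min_dist see
#'   [run_config()].
#' @param umap2 also compute a 2-D UMAP for plotting.
#' @param seed random seed.
#' @return a list of class `embeddings`: `pca` (cells x n_pcs), `umap3`
#'   (cells x 3), optional `umap2`, and `snn`, a weighted undirected
#'   [igraph::graph] on the cells.
#' @export
embed_cells <- function(nm, hvg, n_pcs = 50, knn_k = 20, snn_prune = 1 / 15,
                        umap_n_neighbors = 30, umap_min_dist = 0.3,
                        umap2 = FALSE, seed = 1) {
  check_cells_by_genes(nm, "embed_cells")
  if (length(hvg) == 0) stop("embed_cells: empty hvg list", call. = FALSE)
  if (!all(hvg %in% colnames(nm)))
    stop("embed_cells: hvg symbols missing from matrix", call. = FALSE)
  if (n_pcs > min(nrow(nm), length(hvg)))
    stop("embed_cells: n_pcs exceeds min(cells, hvg)", call. = FALSE)

  x <- nm[, hvg, drop = FALSE]
  mu <- Matrix::colMeans(x)
  sumsq <- Matrix::colSums(x ^ 2)
  sd <- sqrt(pmax((sumsq - nrow(x) * mu ^ 2) / max(nrow(x) - 1, 1), 0))
  keep <- sd > 0
  if (!any(keep))
    stop("embed_cells: all hvg have zero variance", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  mu <- mu[keep]; sd <- sd[keep]

  set.seed(stage_seed(seed, "pca"))
  n_pcs_eff <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  sv <- irlba::irlba(x, nv = n_pcs_eff, center = mu, scale = sd)
  pca <- sv$u %*% diag(sv$d, n_pcs_eff, n_pcs_eff)
  rownames(pca) <- rownames(nm)
  colnames(pca) <- paste0("PC", seq_len(ncol(pca)))

  snn <- build_snn(pca, k = knn_k, prune = snn_prune)

  set.seed(stage_seed(seed, "umap3"))
  umap3 <- uwot::umap(pca, n_components = 3,
                      n_neighbors = umap_n_neighbors,
                      min_dist = umap_min_dist, n_threads = 1,
                      n_sgd_threads = 1)
  rownames(umap3) <- rownames(nm)
  out <- list(pca = pca, umap3 = umap3, snn = snn)
  if (umap2) {
    set.seed(stage_seed(seed, "umap2"))
    out$umap2 <- uwot::umap(pca, n_components = 2,
                            n_neighbors = umap_n_neighbors,
                            min_dist = umap_min_dist, n_threads = 1,
                            n_sgd_threads = 1)
    rownames(out$umap2) <- rownames(nm)
  }
  structure(out, class = "embeddings")
}

#' Shared-nearest-neighbor graph from an embedding
#'
#' For every cell the `k` nearest neighbors (itself included) are found by
#' exact Euclidean search; the SNN weight of a cell pair is the Jaccard
#' similarity of their neighbor sets, `|N(i) & N(j)| / |N(i) | N(j)|`.
#' Weights below `prune` are removed, as are self-loops.
#'
#' @param emb cells x dims numeric matrix with cell rownames.
#' @param k neighborhood size.
#' @param prune minimum retained weight.
#' @return a weighted undirected [igraph::graph] whose vertex names are the
#'   cell ids.
#' @export
build_snn <- function(emb, k = 20, prune = 1 / 15) {
  n <- nrow(emb)
  k <- min(k, n)
  nn <- RANN::nn2(emb, emb, k = k)$nn.idx
  # cells x cells membership matrix: b[i, j] = 1 iff j is a neighbor of i
  b <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(b)
  shared <- as(shared, "CsparseMatrix")
  w <- shared
  w@x <- shared@x / (2 * k - shared@x)  # Jaccard: |union| = 2k - |intersection|
  w@x[w@x < prune] <- 0
  w <- Matrix::drop0(w)
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  dimnames(w) <- list(rownames(emb), rownames(emb))
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
}

#' @export
print.embeddings <- function(x, ...) {
  cat(sprintf("<embeddings> %d cells: PCA %d dims, UMAP 3-D%s, SNN %d edges\n",
              nrow(x$pca), ncol(x$pca),
              if (!is.null(x$umap2)) " + 2-D" else "",
              igraph::ecount(x$snn)))
  invisible(x)
}
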