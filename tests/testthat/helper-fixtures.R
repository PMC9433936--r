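# Shared fixtures, built in code at test time.

# Tiny dense count matrix with controllable dimnames.
tiny_counts <- function(n_cells = 3, n_genes = 4, seed = 42, max_count = 9) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1, n_cells * n_genes, replace = TRUE) - 1L,
              nrow = n_cells,
              dimnames = list(paste0("c", seq_len(n_cells)),
                              paste0("g", seq_len(n_genes))))
  count_matrix(m)
}

# Write a 10x-convention directory by hand (independent of write_10x_mtx).
write_tiny_10x <- function(counts_genes_by_cells, barcodes, symbols, dir,
                           features_name = "features.tsv", ids = symbols) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as(methods::as(counts_genes_by_cells, "dMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(paste(ids, symbols, "Gene Expression", sep = "\t"),
             file.path(dir, features_name))
  dir
}

# Log-normal-expression normalized matrix for scoring tests.
lognormal_norm_matrix <- function(n_cells = 20, n_genes = 60, seed = 7) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_cells * n_genes,
                           mu = rep(exp(rnorm(n_genes, 1, 1)),
                                    each = n_cells),
                           size = 2),
                   nrow = n_cells,
                   dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                                   sprintf("g%02d", seq_len(n_genes))))
  normalize_counts(count_matrix(counts))
}

# A small synthetic bundle shared by the heavier unit tests.
small_fixture <- function(n_cells = 2000, seed = 3)
  synth_generate(synth_spec(n_cells = n_cells, seed = seed))

# Independent brute-force re-implementation of the binned-control module
# score, following the documented steps (i)-(iv) directly on a dense matrix.
brute_module_score <- function(nm_dense, target_genes, n_bins, n_ctrl, seed) {
  genes <- colnames(nm_dense)
  means <- colMeans(nm_dense)
  ord <- order(means, genes)
  bin_of_rank <- as.integer(cut(seq_along(genes), breaks = min(n_bins, length(genes)),
                                labels = FALSE))
  bins <- integer(length(genes)); bins[ord] <- bin_of_rank
  names(bins) <- genes
  set.seed(seed)
  ctrl <- character(0)
  for (g in target_genes) {
    cand <- setdiff(genes[bins == bins[[g]]], target_genes)
    if (length(cand) == 0) next
    ctrl <- c(ctrl, sample(cand, n_ctrl, replace = length(cand) < n_ctrl))
  }
  ctrl <- unique(ctrl)
  rowMeans(nm_dense[, target_genes, drop = FALSE]) -
    rowMeans(nm_dense[, ctrl, drop = FALSE])
}
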