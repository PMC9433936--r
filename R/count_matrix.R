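#' Construct a validated cell-by-gene count matrix
#'
#' The package-wide convention for UMI counts is a sparse `dgCMatrix` with
#' cells in rows and genes in columns, carrying unique cell barcodes as
#' rownames and unique gene symbols as colnames. This constructor validates
#' those invariants and returns the matrix in that convention.
#'
#' @param counts matrix-like of non-negative integers, cells x genes. Dense
#'   matrices are converted to sparse.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames.
#' @param gene_ids character vector of unique gene symbols; defaults to
#'   existing colnames.
#' @return a `dgCMatrix`, cells x genes, with validated dimnames.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("count_matrix: cell_ids and gene_ids are required", call. = FALSE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop("count_matrix: dimensions do not match id lengths", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("count_matrix: duplicate cell_ids", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("count_matrix: duplicate gene_ids", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stop("count_matrix: counts must be finite and non-negative", call. = FALSE)
  dimnames(counts) <- list(as.character(cell_ids), as.character(gene_ids))
  counts
}

#' Validate that an object follows the cell-by-gene matrix convention
#'
#' @param m a matrix-like object (counts or normalized values).
#' @param what label used in error messages.
#' @return the (possibly sparse-coerced) matrix, invisibly usable downstream.
#' @keywords internal
check_cells_by_genes <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, ": cell and gene names are required", call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop(what, ": duplicate cell or gene identifiers", call. = FALSE)
  invisible(m)
}

#' Make duplicated gene symbols unique
#'
#' Duplicates are suffixed `.1`, `.2`, ... in order of appearance, matching
#' the usual convention of 10x readers.
#'
#' @param x character vector of symbols.
#' @return character vector of the same length with unique entries.
#' @keywords internal
make_unique_symbols <- function(x) {
  x <- as.character(x)
  dup <- duplicated(x)
  if (!any(dup)) return(x)
  counter <- new.env(parent = emptyenv())
  out <- x
  for (i in which(dup)) {
    k <- x[i]
    n <- if (is.null(counter[[k]])) 1L else counter[[k]] + 1L
    # skip suffixes that collide with symbols already present
    while (paste0(k, ".", n) %in% x) n <- n + 1L
    counter[[k]] <- n
    out[i] <- paste0(k, ".", n)
  }
  out
}
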