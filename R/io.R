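#' Read a 10x-convention MatrixMarket directory
#'
#' Reads the standard triplet layout produced by droplet pipelines: a
#' MatrixMarket file with genes in rows and cells in columns plus barcode and
#' feature tables. Both the v2 (`genes.tsv`) and v3 (`features.tsv`,
#' optionally gzipped) naming conventions are accepted; when a features table
#' has two or more columns, column 2 is taken as the gene symbol (column 1 is
#' typically an Ensembl id and is ignored: gene symbols are the join key for
#' all gene sets). Duplicate symbols are made unique by suffixing.
#'
#' @param dir path to the directory holding `matrix.mtx[.gz]`,
#'   `barcodes.tsv[.gz]` and `features.tsv[.gz]` or `genes.tsv[.gz]`.
#' @return a cells x genes sparse count matrix (see [count_matrix()]).
#' @export
read_10x_mtx <- function(dir) {
  if (!dir.exists(dir))
    stop("read_10x_mtx: directory not found: ", dir, call. = FALSE)
  find1 <- function(names) {
    for (n in names) {
      p <- file.path(dir, n)
      if (file.exists(p)) return(p)
    }
    stop("read_10x_mtx: none of [", paste(names, collapse = ", "),
         "] found in ", dir, call. = FALSE)
  }
  mtx_path <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  bc_path  <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  ft_path  <- find1(c("features.tsv", "features.tsv.gz",
                      "genes.tsv", "genes.tsv.gz"))

  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e)
    stop("read_10x_mtx: malformed MatrixMarket file: ", conditionMessage(e),
         call. = FALSE))
  barcodes <- readLines(bc_path)
  feats <- read.delim(ft_path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]

  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes))
    stop("read_10x_mtx: matrix is ", nrow(m), " x ", ncol(m),
         " but found ", length(symbols), " features and ",
         length(barcodes), " barcodes", call. = FALSE)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("read_10x_mtx: empty matrix", call. = FALSE)

  count_matrix(Matrix::t(m), cell_ids = barcodes,
               gene_ids = make_unique_symbols(symbols))
}

#' Write a count matrix as a 10x-convention MatrixMarket directory
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx` (genes x cells),
#' `barcodes.tsv` and a two-column `features.tsv` (id, symbol).
#'
#' @param m cells x genes sparse count matrix.
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_10x_mtx <- function(m, dir) {
  check_cells_by_genes(m, "write_10x_mtx")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = colnames(m), symbol = colnames(m)),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Construct a gene set
#'
#' @param name set label, e.g. a pathway identifier such as "GO:0006096" or a
#'   free-text marker-list name.
#' @param genes character vector of gene symbols; duplicates are removed.
#' @param direction `"positive"` for a selector whose threshold exceedance
#'   marks stress (e.g. glycolysis, ER stress), `"negative"` for a lineage
#'   filter whose exceedance vetoes a stressed call (e.g. gliogenesis).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (length(genes) == 0L)
    stop("gene_set: '", name, "' has no genes", call. = FALSE)
  structure(list(name = as.character(name), genes = genes,
                 direction = direction, dropped = character(0)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d genes", x$name, x$direction,
              length(x$genes)))
  if (length(x$dropped))
    cat(sprintf(" [%d undetected symbols dropped]", length(x$dropped)))
  cat("\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name TAB description TAB gene symbols. All sets default
#' to positive direction; flip individual sets with [set_direction()] or the
#' `direction` argument of [gene_set()].
#'
#' @param path GMT file (plain or gzipped).
#' @return named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop("read_gmt: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("read_gmt: line ", i, " has fewer than 3 tab-separated fields",
           call. = FALSE)
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$name, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Set the direction of a gene set
#'
#' @param gs a [gene_set()].
#' @param direction `"positive"` or `"negative"`.
#' @return the modified set.
#' @export
set_direction <- function(gs, direction = c("positive", "negative")) {
  stopifnot(inherits(gs, "gene_set"))
  gs$direction <- match.arg(direction)
  gs
}

#' Write stress calls to TSV
#'
#' Schema: `cell_id`, `granule_id`, one column per granule-level score, and
#' `is_stressed`; one row per cell, ordered by `cell_id`.
#'
#' @param calls a `stress_call` object (see [combine_and_call()]).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "stress_call"))
  df <- as.data.frame(calls)
  df <- df[order(df$cell_id), , drop = FALSE]
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_calls: cannot write ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read stress calls written by [write_calls()]
#'
#' @param path TSV path.
#' @return data.frame with `cell_id`, `granule_id`, score columns and logical
#'   `is_stressed`.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "granule_id", "is_stressed")
  if (!all(need %in% names(df)))
    stop("read_calls: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df$cell_id <- as.character(df$cell_id)
  df$is_stressed <- as.logical(df$is_stressed)
  df
}
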