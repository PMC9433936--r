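#' Restrict a gene set to detected genes
#'
#' Keeps the symbols present in the matrix with nonzero total expression and
#' records the dropped symbols in the set's `dropped` field for audit.
#'
#' @param gs a [gene_set()].
#' @param nm normalized cells x genes matrix.
#' @param min_set_size minimum surviving genes; fewer is an error naming the
#'   set.
#' @return the restricted `gene_set`.
#' @export
intersect_set <- function(gs, nm, min_set_size = 5) {
  stopifnot(inherits(gs, "gene_set"))
  check_cells_by_genes(nm, "intersect_set")
  detected <- colnames(nm)[Matrix::colSums(nm) > 0]
  keep <- gs$genes %in% detected
  dropped <- gs$genes[!keep]
  gs$dropped <- c(gs$dropped, dropped)
  gs$genes <- gs$genes[keep]
  if (length(gs$genes) < min_set_size)
    stop("intersect_set: gene set '", gs$name, "' retains ",
         length(gs$genes), " detected genes (minimum ", min_set_size, ")",
         call. = FALSE)
  gs
}

#' Gene-set activity score with expression-binned control genes
#'
#' Per-cell score for one gene set, controlled for cell quality and depth:
#' (i) the mean normalized expression of every gene over all cells is
#' computed; (ii) genes are partitioned into `n_bins` equal-frequency bins of
#' that mean (ties broken by symbol order); (iii) for each target gene,
#' `n_ctrl` control genes are drawn from its bin — uniformly without
#' replacement, with replacement only when the bin holds fewer candidates —
#' excluding the target set itself; the control pool is the union of all
#' draws; (iv) the score of a cell is its mean expression over the target
#' genes minus its mean expression over the control pool.
#'
#' @param nm normalized matrix.
#' @param gs a [gene_set()] already restricted to detected genes (see
#'   [intersect_set()]); undetected members are an error.
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl control genes per target gene (default 100).
#' @param seed random seed for control sampling.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(nm, gs, n_bins = 25, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(gs, "gene_set"), n_bins >= 1, n_ctrl >= 1)
  check_cells_by_genes(nm, "module_score")
  genes <- colnames(nm)
  if (!all(gs$genes %in% genes))
    stop("module_score: set '", gs$name, "' contains genes absent from the ",
         "matrix; run intersect_set() first", call. = FALSE)
  detected <- Matrix::colSums(nm) > 0
  if (!all(detected[gs$genes]))
    stop("module_score: set '", gs$name, "' contains undetected genes; run ",
         "intersect_set() first", call. = FALSE)

  bins <- bin_genes(Matrix::colMeans(nm), genes, n_bins)

  set.seed(seed)
  ctrl <- character(0)
  for (g in gs$genes) {
    candidates <- setdiff(names(bins)[bins == bins[[g]]], gs$genes)
    if (length(candidates) == 0) next
    ctrl <- c(ctrl, sample(candidates, n_ctrl,
                           replace = length(candidates) < n_ctrl))
  }
  ctrl <- unique(ctrl)
  if (length(ctrl) == 0)
    stop("module_score: no control genes available for set '", gs$name, "'",
         call. = FALSE)

  target_mean <- Matrix::rowMeans(nm[, gs$genes, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(nm[, ctrl, drop = FALSE])
  score <- as.numeric(target_mean - ctrl_mean)
  names(score) <- rownames(nm)
  score
}

# Equal-frequency bins of per-gene mean expression; ties broken by symbol
# order so binning depends only on ranks (hence is shift-invariant).
bin_genes <- function(means, genes, n_bins) {
  ord <- order(means, genes)
  n <- length(genes)
  n_bins <- min(n_bins, n)
  # split ranks into n_bins contiguous, near-equal blocks
  bin_of_rank <- if (n_bins == 1) rep(1L, n)
  else as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  bins <- integer(n)
  bins[ord] <- bin_of_rank
  names(bins) <- genes
  bins
}

#' Score a normalized matrix for a list of gene sets
#'
#' One [module_score()] column per set; each set is first restricted to
#' detected genes. Failures are collected across sets and reported together.
#'
#' @param nm normalized matrix.
#' @param sets named list of [gene_set()] objects with unique names.
#' @param cfg a [run_config()] supplying `n_bins`, `n_ctrl`, `min_set_size`
#'   and the seed.
#' @return an object of class `score_table`: list with `scores` (cells x
#'   sets numeric matrix), `sets` (the intersected sets, with dropped
#'   symbols) and `seed`.
#' @export
score_all <- function(nm, sets, cfg = run_config()) {
  if (length(sets) == 0) stop("score_all: no gene sets", call. = FALSE)
  nm_names <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm_names))
    stop("score_all: duplicate gene set names: ",
         paste(unique(nm_names[duplicated(nm_names)]), collapse = ", "),
         call. = FALSE)
  failures <- character(0)
  used <- list()
  cols <- list()
  for (s in sets) {
    res <- tryCatch({
      si <- intersect_set(s, nm, min_set_size = cfg$min_set_size)
      list(set = si,
           score = module_score(nm, si, n_bins = cfg$n_bins,
                                n_ctrl = cfg$n_ctrl,
                                seed = stage_seed(cfg$seed,
                                                  paste0("score:", s$name))))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, paste0(s$name, ": ", res))
    } else {
      used[[res$set$name]] <- res$set
      cols[[res$set$name]] <- res$score
    }
  }
  if (length(failures))
    stop("score_all: scoring failed for ", length(failures), " set(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  scores <- do.call(cbind, cols)
  rownames(scores) <- rownames(nm)
  structure(list(scores = scores, sets = used, seed = cfg$seed),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d cells x %d scores: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(colnames(x$scores), collapse = ", ")))
  invisible(x)
}

#' Write per-cell scores as TSV
#'
#' @param st a `score_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scores <- function(st, path) {
  stopifnot(inherits(st, "score_table"))
  df <- data.frame(cell_id = rownames(st$scores), st$scores,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell score TSV written by [write_scores()]
#'
#' @param path TSV path.
#' @return a `score_table` (without set provenance).
#' @export
read_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "cell_id")
    stop("read_scores: first column must be cell_id", call. = FALSE)
  scores <- as.matrix(df[, -1, drop = FALSE])
  rownames(scores) <- df$cell_id
  structure(list(scores = scores, sets = list(), seed = NA_integer_),
            class = "score_table")
}
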