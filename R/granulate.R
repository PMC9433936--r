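#' Construct a granule partition
#'
#' @param labels per-cell granule labels (named by cell id).
#' @param resolution the clustering resolution that produced them.
#' @param reassigned logical flag per cell, `TRUE` where the label came from
#'   small-granule reassignment rather than clustering.
#' @return an object of class `granule_partition` with fields `labels`,
#'   `resolution`, `sizes` (granule id -> cell count) and `reassigned`.
#' @export
granule_partition <- function(labels, resolution = NA_real_,
                              reassigned = NULL) {
  if (is.null(names(labels)))
    stop("granule_partition: labels must be named by cell id", call. = FALSE)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(reassigned))
    reassigned <- stats::setNames(rep(FALSE, length(labels)), names(labels))
  sizes <- table(labels)
  structure(list(labels = labels, resolution = resolution,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 reassigned = reassigned),
            class = "granule_partition")
}

#' @export
print.granule_partition <- function(x, ...) {
  cat(sprintf(paste0("<granule_partition> %d cells in %d granules ",
                     "(median size %s, min %d, max %d; resolution %s)\n"),
              length(x$labels), length(x$sizes),
              format(stats::median(x$sizes)), min(x$sizes), max(x$sizes),
              format(x$resolution)))
  if (any(x$reassigned))
    cat(sprintf("  %d cells reassigned from undersized granules\n",
                sum(x$reassigned)))
  invisible(x)
}

#' Louvain clustering of the SNN graph at a fixed resolution
#'
#' Multilevel modularity optimization with a resolution parameter;
#' deterministic for a given seed.
#'
#' @param snn weighted undirected [igraph::graph] with cell-id vertex names.
#' @param resolution positive resolution parameter; higher values give more,
#'   smaller granules.
#' @param seed random seed.
#' @return a [granule_partition()].
#' @export
cluster_at <- function(snn, resolution, seed = 1) {
  if (resolution <= 0)
    stop("cluster_at: resolution must be positive", call. = FALSE)
  if (igraph::vcount(snn) == 0)
    stop("cluster_at: empty graph", call. = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(snn, resolution = resolution)
  labels <- stats::setNames(paste0("g", igraph::membership(comm)),
                            igraph::V(snn)$name)
  granule_partition(labels, resolution = resolution)
}

#' Automatic clustering-resolution search for a target median granule size
#'
#' Finds a resolution whose partition has a median granule size inside
#' `[lower_median, upper_median]` (closed interval). The search starts at
#' resolution 1, expands geometrically (doubling when granules are too
#' large, halving when too small) until the target is bracketed, then
#' bisects; it returns the first partition whose median lands in range,
#' capped at `max_iter` clustering calls.
#'
#' @param snn SNN graph.
#' @param lower_median,upper_median target interval, in cells.
#' @param max_iter maximum clustering calls (default 30).
#' @param seed random seed, reused for every clustering call so the returned
#'   resolution reproduces its partition.
#' @return a [granule_partition()] whose `resolution` field records the
#'   selected resolution.
#' @export
auto_resolution <- function(snn, lower_median = 100, upper_median = 200,
                            max_iter = 30, seed = 1) {
  if (lower_median >= upper_median)
    stop("auto_resolution: lower_median must be < upper_median",
         call. = FALSE)
  n <- igraph::vcount(snn)
  if (n < lower_median)
    stop("auto_resolution: graph has fewer cells (", n,
         ") than lower_median", call. = FALSE)

  tried <- data.frame(resolution = numeric(0), median = numeric(0))
  try_res <- function(res) {
    p <- cluster_at(snn, res, seed = seed)
    tried[nrow(tried) + 1L, ] <<- c(res, stats::median(p$sizes))
    p
  }
  in_range <- function(med) med >= lower_median && med <= upper_median

  # res_low: median too large (resolution too coarse); res_high: too fine
  res_low <- res_high <- NA_real_
  res <- 1
  p <- try_res(res)
  med <- stats::median(p$sizes)
  iter <- 1L
  # geometric expansion until the target interval is bracketed
  while (!in_range(med) && iter < max_iter &&
         (is.na(res_low) || is.na(res_high))) {
    if (med > upper_median) res_low <- res else res_high <- res
    res <- if (med > upper_median) {
      if (is.na(res_high)) res * 2 else (res + res_high) / 2
    } else {
      if (is.na(res_low)) res / 2 else (res + res_low) / 2
    }
    p <- try_res(res)
    med <- stats::median(p$sizes)
    iter <- iter + 1L
  }
  # bisection inside the bracket
  while (!in_range(med) && iter < max_iter) {
    if (med > upper_median) res_low <- res else res_high <- res
    res <- (res_low + res_high) / 2
    p <- try_res(res)
    med <- stats::median(p$sizes)
    iter <- iter + 1L
  }
  if (!in_range(med)) {
    msg <- paste(sprintf("  resolution %.4g -> median %g",
                         tried$resolution, tried$median), collapse = "\n")
    stop("auto_resolution: no resolution with median granule size in [",
         lower_median, ", ", upper_median, "] within ", max_iter,
         " attempts:\n", msg, call. = FALSE)
  }
  p
}

#' Reassign cells from undersized granules to the nearest retained centroid
#'
#' Granules with at least `min_granule` cells are the recipients; their
#' centroids are the means of their members' 3-D UMAP coordinates, computed
#' once before any transfer. Every cell of an undersized granule moves to
#' the recipient with the nearest centroid (Euclidean distance); donor
#' granule ids disappear, so every remaining granule has at least
#' `min_granule` cells.
#'
#' @param p a [granule_partition()].
#' @param umap3 cells x 3 coordinate matrix covering every cell in `p`.
#' @param min_granule size threshold (default 30).
#' @return a [granule_partition()] with `reassigned` flags set.
#' @export
reassign_small <- function(p, umap3, min_granule = 30) {
  stopifnot(inherits(p, "granule_partition"))
  cells <- names(p$labels)
  if (!all(cells %in% rownames(umap3)))
    stop("reassign_small: umap3 must cover every cell", call. = FALSE)
  umap3 <- umap3[cells, , drop = FALSE]

  recipients <- names(p$sizes)[p$sizes >= min_granule]
  if (length(recipients) == 0)
    stop("reassign_small: no granule reaches ", min_granule,
         " cells; lower the clustering resolution", call. = FALSE)
  donors <- setdiff(names(p$sizes), recipients)
  if (length(donors) == 0) return(p)

  centroids <- t(vapply(recipients, function(g)
    colMeans(umap3[p$labels == g, , drop = FALSE]), numeric(3)))

  labels <- p$labels
  moved <- names(labels)[labels %in% donors]
  # squared Euclidean distances cells x recipients
  d2 <- outer(rowSums(umap3[moved, , drop = FALSE] ^ 2),
              rowSums(centroids ^ 2), "+") -
    2 * umap3[moved, , drop = FALSE] %*% t(centroids)
  nearest <- recipients[max.col(-d2, ties.method = "first")]
  labels[moved] <- nearest
  reassigned <- p$reassigned
  reassigned[moved] <- TRUE
  granule_partition(labels, resolution = p$resolution,
                    reassigned = reassigned)
}

#' Write a granule partition as a two-column TSV
#'
#' @param p a [granule_partition()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "granule_partition"))
  write.table(data.frame(cell_id = names(p$labels), granule_id = p$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a granule partition from a two-column TSV
#'
#' Enables granulation by external clustering tools.
#'
#' @param path TSV with columns `cell_id`, `granule_id`.
#' @return a [granule_partition()] (resolution `NA`).
#' @export
read_partition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "granule_id") %in% names(df)))
    stop("read_partition: need columns cell_id, granule_id", call. = FALSE)
  granule_partition(stats::setNames(as.character(df$granule_id),
                                    df$cell_id))
}
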