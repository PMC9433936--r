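#' Average per-cell scores within granules
#'
#' The granule score is the unweighted arithmetic mean of the member cells'
#' scores, so each granule contributes one observation regardless of its
#' cell count.
#'
#' @param st a `score_table` from [score_all()].
#' @param p a [granule_partition()] covering the same cells.
#' @return an object of class `granule_scores`: list with `scores`
#'   (granules x score-names matrix) and `n_cells` (per-granule cell count).
#' @export
aggregate_scores <- function(st, p) {
  stopifnot(inherits(st, "score_table"), inherits(p, "granule_partition"))
  cells <- rownames(st$scores)
  if (!setequal(cells, names(p$labels)))
    stop("aggregate_scores: partition and score table cover different cells",
         call. = FALSE)
  lab <- factor(p$labels[cells])
  g <- apply(st$scores, 2, function(col) tapply(col, lab, mean))
  g <- matrix(g, nrow = nlevels(lab),
              dimnames = list(levels(lab), colnames(st$scores)))
  structure(list(scores = g,
                 n_cells = p$sizes[levels(lab)]),
            class = "granule_scores")
}

#' @export
print.granule_scores <- function(x, ...) {
  cat(sprintf("<granule_scores> %d granules x %d scores\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Automatic upper threshold from a Gaussian fit with lower-tail scale
#'
#' The non-stressed bulk of granule scores is modelled as Gaussian with a
#' possibly contaminated upper tail: the location `m` is the median of the
#' scores, the scale `s` is the root-mean-square deviation about `m` of the
#' scores strictly below `m` (population divisor; 0 if none lie below), and
#' the threshold is the theoretical `q`-quantile of that fit,
#' `t = m + qnorm(q) * s`.
#'
#' @param g_scores numeric vector of per-granule (or per-cell) scores; at
#'   least 3 required.
#' @param q quantile (default 0.99).
#' @param score,direction,source metadata recorded in the fit.
#' @return an object of class `threshold_fit` with fields `score`,
#'   `direction`, `m`, `s`, `q`, `t`, `source`, `n`.
#' @export
fit_threshold <- function(g_scores, q = 0.99, score = "score",
                          direction = c("positive", "negative"),
                          source = c("auto", "manual")) {
  direction <- match.arg(direction)
  source <- match.arg(source)
  g_scores <- as.numeric(g_scores)
  if (any(!is.finite(g_scores)))
    stop("fit_threshold: non-finite scores", call. = FALSE)
  if (length(g_scores) < 3)
    stop("fit_threshold: need at least 3 scores", call. = FALSE)
  stopifnot(q > 0, q < 1)
  m <- stats::median(g_scores)
  lower <- g_scores[g_scores < m]
  s <- if (length(lower)) sqrt(mean((lower - m) ^ 2)) else 0
  structure(list(score = score, direction = direction, m = m, s = s,
                 q = q, t = m + stats::qnorm(q) * s, source = source,
                 n = length(g_scores)),
            class = "threshold_fit")
}

#' Manually specified threshold
#'
#' @param t the cutoff.
#' @param score,direction metadata as in [fit_threshold()].
#' @return a `threshold_fit` with `source = "manual"` (`m`, `s` are `NA`).
#' @export
manual_threshold <- function(t, score = "score",
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  structure(list(score = score, direction = direction, m = NA_real_,
                 s = NA_real_, q = NA_real_, t = t, source = "manual",
                 n = NA_integer_),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> %s (%s, %s): t = %.4g", x$score, x$direction,
              x$source, x$t))
  if (x$source == "auto")
    cat(sprintf("  [m = %.4g, s = %.4g, q = %g, n = %d]",
                x$m, x$s, x$q, x$n))
  cat("\n")
  invisible(x)
}

#' Combine thresholded scores into stress calls
#'
#' A granule is stressed iff at least one positive-direction score exceeds
#' its threshold (strictly) AND no negative-direction score exceeds its own
#' threshold: exceedance of a negative (lineage) score vetoes the call,
#' protecting cell types with natively high scores. Per-cell labels are the
#' granule labels broadcast to member cells.
#'
#' @param gt a `granule_scores` from [aggregate_scores()].
#' @param fits list of `threshold_fit` objects, one per score column; at
#'   least one must be positive-direction.
#' @param p the [granule_partition()] used for aggregation.
#' @return an object of class `stress_call`: `granule_stressed` (named
#'   logical per granule), `cell_stressed` (named logical per cell),
#'   `fits`, `granule_scores`, `mode = "granular"`.
#' @export
combine_and_call <- function(gt, fits, p) {
  stopifnot(inherits(gt, "granule_scores"), inherits(p, "granule_partition"))
  call_from_matrix(gt$scores, fits, labels = p$labels, mode = "granular",
                   granule_scores = gt)
}

call_from_matrix <- function(score_mat, fits, labels = NULL,
                             mode = c("granular", "single_cell"),
                             granule_scores = NULL) {
  mode <- match.arg(mode)
  fit_scores <- vapply(fits, `[[`, "", "score")
  missing <- setdiff(fit_scores, colnames(score_mat))
  if (length(missing))
    stop("stress call: no score column for threshold(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dirs <- vapply(fits, `[[`, "", "direction")
  if (!any(dirs == "positive"))
    stop("stress call: at least one positive-direction threshold required",
         call. = FALSE)
  exceeds <- vapply(fits, function(f) score_mat[, f$score] > f$t,
                    logical(nrow(score_mat)))
  exceeds <- matrix(exceeds, nrow = nrow(score_mat),
                    dimnames = list(rownames(score_mat), NULL))
  pos <- apply(exceeds[, dirs == "positive", drop = FALSE], 1, any)
  neg <- if (any(dirs == "negative"))
    apply(exceeds[, dirs == "negative", drop = FALSE], 1, any)
  else rep(FALSE, nrow(score_mat))
  stressed <- pos & !neg

  if (mode == "granular") {
    cell_stressed <- stats::setNames(stressed[labels], names(labels))
    granule_stressed <- stressed
  } else {
    cell_stressed <- stressed
    granule_stressed <- NULL
  }
  structure(list(granule_stressed = granule_stressed,
                 cell_stressed = cell_stressed,
                 labels = labels, fits = fits,
                 granule_scores = granule_scores, mode = mode),
            class = "stress_call")
}

#' Stress calls from per-cell scores, skipping granule aggregation
#'
#' Applies the identical threshold-fitting and combination logic directly to
#' the per-cell scores. Because single-cell scores are noisier than granule
#' averages, the quantile usually needs to be raised (or tuned to a target
#' stressed-cell count) via `quantile_override`.
#'
#' @param st a `score_table`.
#' @param directions named character vector mapping score names to
#'   `"positive"` / `"negative"`.
#' @param q quantile for the automatic fits (default 0.99).
#' @param quantile_override if supplied, replaces `q`.
#' @param manual_thresholds optional named numeric overrides.
#' @return a `stress_call` with `mode = "single_cell"` and granule fields
#'   `NULL`.
#' @export
single_cell_call <- function(st, directions, q = 0.99,
                             quantile_override = NULL,
                             manual_thresholds = NULL) {
  stopifnot(inherits(st, "score_table"))
  if (!is.null(quantile_override)) q <- quantile_override
  fits <- fit_all_thresholds(st$scores, directions, q = q,
                             manual_thresholds = manual_thresholds)
  call_from_matrix(st$scores, fits, mode = "single_cell")
}

#' Fit thresholds for every column of a score matrix
#'
#' @param score_mat granules-or-cells x scores matrix.
#' @param directions named character vector (`"positive"`/`"negative"`) for
#'   every column.
#' @param q quantile.
#' @param manual_thresholds optional named numeric vector; named scores get a
#'   [manual_threshold()] instead of the automatic fit.
#' @return named list of `threshold_fit` objects.
#' @export
fit_all_thresholds <- function(score_mat, directions, q = 0.99,
                               manual_thresholds = NULL) {
  miss <- setdiff(colnames(score_mat), names(directions))
  if (length(miss))
    stop("fit_all_thresholds: no direction given for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  fits <- lapply(colnames(score_mat), function(s) {
    if (!is.null(manual_thresholds) && s %in% names(manual_thresholds))
      manual_threshold(manual_thresholds[[s]], score = s,
                       direction = directions[[s]])
    else
      fit_threshold(score_mat[, s], q = q, score = s,
                    direction = directions[[s]])
  })
  stats::setNames(fits, colnames(score_mat))
}

#' @export
print.stress_call <- function(x, ...) {
  n <- length(x$cell_stressed)
  cat(sprintf("<stress_call> mode %s: %d / %d cells stressed (%.1f%%)\n",
              x$mode, sum(x$cell_stressed), n,
              100 * mean(x$cell_stressed)))
  if (!is.null(x$granule_stressed))
    cat(sprintf("  %d / %d granules stressed\n", sum(x$granule_stressed),
                length(x$granule_stressed)))
  invisible(x)
}

#' @export
as.data.frame.stress_call <- function(x, ...) {
  cells <- names(x$cell_stressed)
  if (x$mode == "granular") {
    gran <- x$labels[cells]
    gs <- x$granule_scores$scores[gran, , drop = FALSE]
    df <- data.frame(cell_id = cells, granule_id = unname(gran),
                     gs, row.names = NULL, check.names = FALSE)
  } else {
    df <- data.frame(cell_id = cells, granule_id = NA_character_,
                     row.names = NULL)
  }
  df$is_stressed <- unname(x$cell_stressed)
  df
}

#' Remove stressed cells from a matrix
#'
#' Returns the matrix restricted to non-stressed cells. Any embeddings,
#' graphs or granules computed from the full matrix are invalid afterwards
#' and must be recomputed.
#'
#' @param m cells x genes matrix (counts or normalized).
#' @param calls a `stress_call` covering all rows of `m`.
#' @return the filtered matrix.
#' @export
filter_cells <- function(m, calls) {
  stopifnot(inherits(calls, "stress_call"))
  cells <- rownames(m)
  if (!all(cells %in% names(calls$cell_stressed)))
    stop("filter_cells: calls do not cover all cells", call. = FALSE)
  keep <- !calls$cell_stressed[cells]
  if (!any(keep))
    stop("filter_cells: every cell is called stressed; refusing to return ",
         "an empty matrix", call. = FALSE)
  m[keep, , drop = FALSE]
}
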