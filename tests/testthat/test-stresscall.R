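make_score_table <- function(scores) {
  structure(list(scores = scores, sets = list(), seed = 1),
            class = "score_table")
}

test_that("granule aggregation is the unweighted group mean", {
  scores <- matrix(c(0.2, 0.4, 1, 2, 3, 9), ncol = 1,
                   dimnames = list(paste0("c", 1:6), "s"))
  p <- granule_partition(setNames(c("a", "a", "b", "b", "b", "c"),
                                  paste0("c", 1:6)))
  gt <- aggregate_scores(make_score_table(scores), p)
  expect_equal(gt$scores[c("a", "b", "c"), "s"], c(a = 0.3, b = 2, c = 9))

  const <- matrix(0.7, 6, 1, dimnames = list(paste0("c", 1:6), "s"))
  expect_equal(unname(aggregate_scores(make_score_table(const), p)$scores[, 1]),
               rep(0.7, 3))

  # random fixture against brute-force group-by
  set.seed(13)
  sc <- matrix(rnorm(200 * 2), 200, 2,
               dimnames = list(paste0("c", 1:200), c("x", "y")))
  lab <- setNames(sample(paste0("g", 1:9), 200, replace = TRUE),
                  rownames(sc))
  gt2 <- aggregate_scores(make_score_table(sc), granule_partition(lab))
  for (g in unique(lab)) for (s in c("x", "y"))
    expect_equal(gt2$scores[g, s], mean(sc[names(lab)[lab == g], s]))

  bad <- granule_partition(setNames("a", "other_cell"))
  expect_error(aggregate_scores(make_score_table(scores), bad),
               "different cells")
})

test_that("threshold fit uses median location and lower-tail RMS scale", {
  # degenerate: constant scores
  f0 <- fit_threshold(rep(3, 10))
  expect_equal(f0$m, 3)
  expect_equal(f0$s, 0)
  expect_equal(f0$t, 3)

  # hand arithmetic on 1..100
  x <- 1:100
  f <- fit_threshold(x, q = 0.99)
  m_oracle <- 50.5
  s_oracle <- sqrt(mean((1:50 - 50.5) ^ 2))
  expect_equal(f$m, m_oracle)
  expect_equal(f$s, s_oracle)
  expect_equal(f$t, m_oracle + qnorm(0.99) * s_oracle)

  expect_error(fit_threshold(c(1, 2, NA, 4)), "non-finite")
  expect_error(fit_threshold(c(1, 2)), "at least 3")
})

test_that("threshold converges to the Gaussian quantile on null scores", {
  set.seed(101)
  x <- rnorm(1e5)
  f <- fit_threshold(x, q = 0.99)
  expect_lt(abs(f$t - qnorm(0.99)), 0.05)
})

test_that("threshold is monotone in q and affine-equivariant", {
  set.seed(17)
  x <- rnorm(500, 2, 3)
  qs <- c(0.6, 0.8, 0.9, 0.99, 0.999)
  ts <- vapply(qs, function(q) fit_threshold(x, q)$t, 0)
  expect_true(all(diff(ts) >= 0))

  a <- 2.5; b <- -1.3
  f1 <- fit_threshold(x, 0.99)
  f2 <- fit_threshold(a * x + b, 0.99)
  expect_equal(f2$t, a * f1$t + b, tolerance = 1e-10)
  expect_equal(f2$m, a * f1$m + b, tolerance = 1e-10)
  expect_equal(f2$s, a * f1$s, tolerance = 1e-10)
})

test_that("calls OR-combine positive scores and are vetoed by negative scores", {
  gscores <- matrix(c(
    # er, gly, glio
    0.0, 0.0, 0.0,    # below everything -> non-stressed
    9.0, 0.0, 0.0,    # crosses er -> stressed
    0.0, 9.0, 0.0,    # crosses gly -> stressed
    9.0, 0.0, 9.0,    # crosses er but vetoed by glio
    0.0, 0.0, 9.0),   # only glio -> non-stressed
    ncol = 3, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), c("er", "gly", "glio")))
  fits <- list(manual_threshold(1, "er", "positive"),
               manual_threshold(1, "gly", "positive"),
               manual_threshold(1, "glio", "negative"))
  labels <- setNames(paste0("g", rep(1:5, each = 2)), paste0("c", 1:10))
  p <- granule_partition(labels)
  gt <- structure(list(scores = gscores, n_cells = p$sizes),
                  class = "granule_scores")
  calls <- combine_and_call(gt, fits, p)
  expect_equal(unname(calls$granule_stressed[paste0("g", 1:5)]),
               c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # per-cell labels broadcast from granules
  expect_equal(unname(calls$cell_stressed),
               unname(calls$granule_stressed[labels]))

  # all granules at their medians -> zero stressed under automatic fits
  same <- matrix(0.5, 5, 1, dimnames = list(paste0("g", 1:5), "er"))
  gt2 <- structure(list(scores = same, n_cells = p$sizes),
                   class = "granule_scores")
  auto <- fit_all_thresholds(same, c(er = "positive"))
  expect_false(any(combine_and_call(gt2, auto, p)$granule_stressed))

  expect_error(combine_and_call(gt, fits["er" == ""], p), "positive")
  expect_error(combine_and_call(
    gt2, list(manual_threshold(1, "nope", "positive")), p), "no score")
})

test_that("a negative filter can only shrink the stressed set", {
  set.seed(23)
  for (rep in 1:10) {
    gscores <- matrix(rnorm(60 * 2), 60, 2,
                      dimnames = list(paste0("g", 1:60), c("pos", "neg")))
    labels <- setNames(paste0("g", sample(1:60, 300, replace = TRUE)),
                       paste0("c", 1:300))
    p <- granule_partition(labels)
    gt <- structure(list(scores = gscores[names(p$sizes), , drop = FALSE],
                         n_cells = p$sizes), class = "granule_scores")
    fits_pos <- fit_all_thresholds(gt$scores[, "pos", drop = FALSE],
                                   c(pos = "positive"), q = 0.8)
    fits_both <- fit_all_thresholds(gt$scores,
                                    c(pos = "positive", neg = "negative"),
                                    q = 0.8)
    s_pos <- combine_and_call(gt, fits_pos, p)$granule_stressed
    s_both <- combine_and_call(gt, fits_both, p)$granule_stressed
    expect_true(all(names(which(s_both)) %in% names(which(s_pos))))
  }
})

test_that("single-cell mode equals granular mode on within-granule-constant scores", {
  labels <- setNames(rep(paste0("g", 1:6), each = 5), paste0("c", 1:30))
  p <- granule_partition(labels)
  gvals <- c(0, 0.1, 0.05, 2, 0.02, 0.08)
  scores <- matrix(gvals[rep(1:6, each = 5)], ncol = 1,
                   dimnames = list(names(labels), "s"))
  st <- make_score_table(scores)

  gt <- aggregate_scores(st, p)
  fits <- fit_all_thresholds(gt$scores, c(s = "positive"), q = 0.9)
  granular <- combine_and_call(gt, fits, p)
  sc <- single_cell_call(st, c(s = "positive"), q = 0.9)
  expect_equal(unname(sc$cell_stressed[names(labels)]),
               unname(granular$cell_stressed[names(labels)]))
  expect_equal(sc$mode, "single_cell")
})

test_that("quantile override near 0.5 flags about half of symmetric null scores", {
  set.seed(31)
  scores <- matrix(rnorm(20000), ncol = 1,
                   dimnames = list(paste0("c", 1:20000), "s"))
  sc <- single_cell_call(make_score_table(scores), c(s = "positive"),
                         quantile_override = 0.5)
  # t = median + 0 * s = median; ~half the cells exceed it
  expect_equal(mean(sc$cell_stressed), 0.5, tolerance = 0.02)
})

test_that("filter_cells removes exactly the called cells", {
  sf <- small_fixture(200)
  m <- sf$counts
  stressed <- setNames(rownames(m) %in% rownames(m)[1:40], rownames(m))
  calls <- structure(list(cell_stressed = stressed,
                          granule_stressed = NULL, labels = NULL,
                          fits = list(), granule_scores = NULL,
                          mode = "single_cell"), class = "stress_call")
  out <- filter_cells(m, calls)
  expect_equal(rownames(out), rownames(m)[41:200])

  none <- calls; none$cell_stressed[] <- FALSE
  expect_equal(dim(filter_cells(m, none)), dim(m))

  all_s <- calls; all_s$cell_stressed[] <- TRUE
  expect_error(filter_cells(m, all_s), "refusing")

  partial <- calls; partial$cell_stressed <- stressed[1:10]
  expect_error(filter_cells(m, partial), "cover")
})

test_that("single-cell scoring is less specific than granular scoring at matched call counts", {
  s <- small_fixture(2000, seed = 9)
  fit <- granufi(s$counts, s$sets,
                 config = run_config(lower_median = 80, upper_median = 160,
                                     seed = 9))
  truth <- setNames(s$truth$stressed, s$truth$cell_id)[rownames(fit$counts)]
  g_pred <- fit$calls$cell_stressed[rownames(fit$counts)]
  n_target <- sum(g_pred)
  directions <- vapply(fit$score_table$sets, `[[`, "", "direction")

  # tune the single-cell quantile to a similar stressed-cell count
  qs <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 0.995, 0.999)
  counts_at_q <- vapply(qs, function(q)
    sum(single_cell_call(fit$score_table, directions,
                         quantile_override = q)$cell_stressed), 0)
  q_star <- qs[which.min(abs(counts_at_q - n_target))]
  sc_pred <- single_cell_call(fit$score_table, directions,
                              quantile_override = q_star)$cell_stressed
  sc_pred <- sc_pred[rownames(fit$counts)]

  specificity <- function(pred) sum(!pred & !truth) / sum(!truth)
  expect_lte(specificity(sc_pred), specificity(g_pred))
})
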