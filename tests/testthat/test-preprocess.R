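test_that("qc_filter applies the three rules conjunctively and strictly", {
  # 3 cells x forced stats: use 700 genes so detected counts are controllable
  n_genes <- 700
  genes <- c("MT-CO1", "RPL3", paste0("g", seq_len(n_genes - 2)))
  build_cell <- function(n_detected, mito_frac, ribo_frac, total = 1000) {
    x <- numeric(n_genes)
    x[1] <- round(total * mito_frac)
    x[2] <- round(total * ribo_frac)
    rest <- total - x[1] - x[2]
    body_genes <- seq(3, 2 + n_detected - 2)
    x[body_genes] <- 1
    x[body_genes[1]] <- x[body_genes[1]] + rest - (n_detected - 2)
    x
  }
  m <- count_matrix(rbind(
    ok = build_cell(600, 0.05, 0.10),
    few_genes = build_cell(400, 0.05, 0.10),
    high_mito = build_cell(600, 0.25, 0.10)),
    gene_ids = genes)
  out <- qc_filter(m, min_genes = 500, max_mito = 0.20, max_ribo = 0.30)
  expect_equal(rownames(out), "ok")
  r <- attr(out, "qc_report")
  expect_equal(r$removed_low_genes, 1)
  expect_equal(r$removed_high_mito, 1)
  expect_equal(r$removed_high_ribo, 0)

  # permissive thresholds are the identity
  all_kept <- qc_filter(m, min_genes = 0, max_mito = 1, max_ribo = 1)
  expect_equal(dim(all_kept), dim(m))

  expect_error(qc_filter(m, min_genes = 10000), "no cells pass")
})

test_that("qc_filter matches a brute-force per-cell rule evaluation", {
  set.seed(11)
  genes <- c(paste0("MT-", 1:5), paste0("RPS", 1:5), paste0("g", 1:90))
  counts <- matrix(rpois(100 * 100, lambda = 2), 100,
                   dimnames = list(paste0("c", 1:100), genes))
  m <- count_matrix(counts)
  out <- qc_filter(m, min_genes = 55, max_mito = 0.12, max_ribo = 0.12)

  keep_oracle <- vapply(seq_len(100), function(i) {
    x <- counts[i, ]
    sum(x > 0) > 55 &&
      sum(x[1:5]) / sum(x) < 0.12 &&
      sum(x[6:10]) / sum(x) < 0.12
  }, logical(1))
  expect_equal(rownames(out), rownames(counts)[keep_oracle])
})

test_that("normalization scales each cell to 10K and log-transforms", {
  m <- count_matrix(matrix(c(10, 9990, 0, 0), 1,
                           dimnames = list("c1", paste0("g", 1:4))))
  nm <- normalize_counts(m)
  expect_equal(nm[1, 1], log1p(10))
  expect_equal(nm[1, 3], 0)

  m2 <- small_fixture(200)$counts
  nm2 <- normalize_counts(m2)
  e <- nm2; e@x <- expm1(e@x)
  totals <- Matrix::rowSums(e)
  expect_true(all(abs(totals - 1e4) < 1e-6))
  expect_true(all(nm2@x >= 0))

  # re-normalizing the back-transform is idempotent
  back <- e
  nm3 <- normalize_counts(count_matrix(back))
  expect_equal(as.matrix(nm3), as.matrix(nm2), tolerance = 1e-12)
})

test_that("all-zero cells normalize to zero rows with a warning", {
  m <- count_matrix(matrix(c(5, 0, 3, 0), 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  m["b", ] <- 0
  expect_warning(nm <- normalize_counts(count_matrix(as.matrix(m))),
                 "zero total")
  expect_equal(as.numeric(nm["b", ]), c(0, 0))
})

test_that("variable-gene ranking matches brute-force log-VMR", {
  nm <- lognormal_norm_matrix(30, 50, seed = 5)
  hvg <- select_hvg(nm, 50)

  dense <- as.matrix(nm)
  e <- expm1(dense)
  lvmr <- vapply(colnames(e), function(g) {
    mu <- mean(e[, g]); v <- var(e[, g])
    if (mu > 0 && v > 0) log(v / mu) else -Inf
  }, 0)
  oracle <- colnames(e)[order(-lvmr, colnames(e))]
  expect_equal(hvg, oracle)
  expect_equal(select_hvg(nm, 10), oracle[1:10])
})

test_that("constant genes rank last and bad n errors", {
  nm0 <- lognormal_norm_matrix(10, 20)
  dense <- as.matrix(nm0)
  dense[, "g01"] <- 0.7  # constant expression: zero variance
  nm <- as(dense, "CsparseMatrix")
  hvg <- select_hvg(nm, 20)
  expect_equal(hvg[20], "g01")
  expect_error(select_hvg(nm, 0), "positive")
  expect_error(select_hvg(nm, 21), "exceeds")
})

test_that("identical cells receive identical principal components", {
  sf <- small_fixture(150)
  counts <- as.matrix(sf$counts)
  counts[2, ] <- counts[1, ]  # plant duplicate cells
  nm <- normalize_counts(count_matrix(counts))
  emb <- embed_cells(nm, select_hvg(nm, 300), n_pcs = 10, knn_k = 5,
                     seed = 1)
  expect_equal(emb$pca[1, ], emb$pca[2, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(nrow(emb$umap3), nrow(nm))
  expect_equal(ncol(emb$umap3), 3)
})

test_that("embedding is reproducible under a fixed seed", {
  sf <- small_fixture(120)
  nm <- normalize_counts(sf$counts)
  hvg <- select_hvg(nm, 200)
  e1 <- embed_cells(nm, hvg, n_pcs = 10, knn_k = 5, seed = 4)
  e2 <- embed_cells(nm, hvg, n_pcs = 10, knn_k = 5, seed = 4)
  expect_identical(e1$pca, e2$pca)
  expect_identical(e1$umap3, e2$umap3)
  expect_true(igraph::identical_graphs(e1$snn, e2$snn))
  expect_error(embed_cells(nm, hvg, n_pcs = 1000, knn_k = 5), "n_pcs")
})

test_that("SNN weights are Jaccard similarities of kNN neighborhoods", {
  set.seed(8)
  emb <- matrix(rnorm(40 * 3), 40,
                dimnames = list(paste0("c", 1:40), NULL))
  k <- 6
  g <- build_snn(emb, k = k, prune = 0.01)

  # brute-force: explicit kNN lists, pairwise Jaccard
  d <- as.matrix(dist(emb))
  nn <- lapply(seq_len(40), function(i) order(d[i, ])[seq_len(k)])
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  for (i in 1:39) for (j in (i + 1):40) {
    jac <- length(intersect(nn[[i]], nn[[j]])) /
      length(union(nn[[i]], nn[[j]]))
    expected <- if (jac < 0.01) 0 else jac
    expect_equal(unname(w[i, j]), expected, tolerance = 1e-12)
  }

  # two cells sharing all k neighbors have weight 1
  emb2 <- rbind(emb, c2dup = emb["c2", ] + 1e-9)
  rownames(emb2) <- c(rownames(emb), "c2dup")
  g2 <- build_snn(emb2, k = k, prune = 0)
  w2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(unname(w2["c2", "c2dup"]), 1)
})
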