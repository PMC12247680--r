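test_that("qc filter applies the strict detected-gene threshold", {
  # cell 1 detects 3 genes, cell 2 detects 4, cell 3 detects 5
  m <- rbind(c(1, 1, 1, 0, 0), c(1, 1, 1, 1, 0), c(2, 1, 1, 1, 3))
  ds <- raw_dataset(m, gene_ids = sprintf("g%d", 1:5))
  kept <- qc_filter(ds, min_genes = 4)
  expect_identical(nrow(kept$matrix), 2L)  # 399-analogue removed
  expect_identical(qc_filter(ds, min_genes = 4)$cell_meta$cell,
                   ds$cell_meta$cell[2:3])  # exactly-at-threshold kept
  # survivor count equals an independent nonzero tally
  set.seed(8)
  big <- matrix(rbinom(200 * 50, 1, 0.4) * rpois(200 * 50, 3), 200, 50)
  dsb <- raw_dataset(big)
  for (thr in c(10, 20, 30))
    expect_identical(nrow(qc_filter(dsb, thr)$matrix),
                     sum(rowSums(big > 0) >= thr))
  # empty dataset passes through
  empty <- raw_dataset(matrix(0L, 0, 5), gene_ids = sprintf("g%d", 1:5))
  expect_identical(nrow(qc_filter(empty, 4)$matrix), 0L)
  expect_error(qc_filter(normalize_log(raw_dataset(m + 1)), 4), "stage")
})

test_that("normalization hits the target sum and the log1p example", {
  # a cell expressing a single gene maps that entry to ln(1 + 1e4)
  m <- rbind(c(5, 0, 0), c(3, 2, 5))
  ds <- raw_dataset(m, gene_ids = c("a", "b", "c"))
  norm <- normalize_log(ds)
  expect_equal(norm$matrix[1, "a"], log(1 + 1e4))
  # per-cell de-logged sums equal the target for every cell
  sums <- Matrix::rowSums(expm1(as.matrix(norm$matrix)))
  expect_equal(unname(sums), rep(1e4, 2), tolerance = 1e-6)
  # identical cells normalize identically
  same <- raw_dataset(rbind(c(2, 4), c(2, 4), c(2, 4)))
  nm <- as.matrix(normalize_log(same)$matrix)
  expect_equal(nm[1, ], nm[2, ], ignore_attr = TRUE)
  expect_equal(nm[2, ], nm[3, ], ignore_attr = TRUE)
  # zero cells are data errors naming the cell
  zero <- raw_dataset(rbind(c(1, 1), c(0, 0)),
                      cell_meta = data.frame(cell = c("good", "bad")))
  expect_error(normalize_log(zero), "bad")
})

test_that("regression removes covariates and scaling clips at the max", {
  set.seed(15)
  n <- 20
  cov1 <- rnorm(n)
  y <- sapply(1:8, function(j) 2 * cov1 + rnorm(n))
  norm <- expression_dataset(y, stage = "normalized",
                             gene_ids = sprintf("g%d", 1:8))
  norm$cell_meta$techcov <- cov1
  scaled <- regress_and_scale(norm, covariates = "techcov")
  # residuals orthogonal to the covariate (independent least squares)
  for (j in 1:8)
    expect_lt(abs(sum(scaled$matrix[, j] * scale(cov1))), 1e-8)
  # and they match residuals from lm() gene by gene, post-standardization
  r3 <- stats::residuals(stats::lm(y[, 3] ~ scale(cov1)))
  expect_equal(unname(scaled$matrix[, 3]), unname(r3 / stats::sd(r3)),
               tolerance = 1e-8)
  expect_true(all(scaled$matrix <= 10))
  expect_error(regress_and_scale(norm, covariates = "nope"), "nope")
  # constant gene becomes all-zero after scaling; the clip bound holds
  cst <- expression_dataset(cbind(rep(2.5, 31), c(rep(0, 30), 9)),
                            stage = "normalized",
                            gene_ids = c("flat", "spike"))
  sc <- regress_and_scale(cst, covariates = character())
  expect_true(all(sc$matrix[, "flat"] == 0))
  expect_lte(max(sc$matrix), 10)
})

test_that("pca recovers planted dimensionality with ordered ratios", {
  set.seed(5)
  y <- matrix(rnorm(120 * 3), 120, 3) %*% matrix(rnorm(3 * 30), 3, 30) +
    matrix(rnorm(120 * 30, 0, 1e-4), 120, 30)
  ds <- expression_dataset(y, stage = "scaled",
                           gene_ids = sprintf("g%d", 1:30))
  pe <- run_pca(ds, n_components = 10)
  expect_identical(pe$n_informative, 3L)
  expect_true(all(diff(pe$variance_ratio) <= 1e-12))
  expect_lte(sum(pe$variance_ratio), 1 + 1e-8)
  # duplicating every cell leaves component directions unchanged up to sign
  ds2 <- expression_dataset(rbind(y, y), stage = "scaled",
                            gene_ids = sprintf("g%d", 1:30))
  pe2 <- run_pca(ds2, n_components = 10)
  for (j in 1:3) {
    al <- abs(sum(pe$rotation[, j] * pe2$rotation[, j]))
    expect_gt(al, 0.999)
  }
  expect_error(run_pca(ds, n_components = 500), "cells")
})

test_that("clustering recovers planted blobs and is deterministic", {
  set.seed(41)
  blob <- function(center, n) sweep(matrix(rnorm(n * 5, 0, 0.2), n, 5),
                                    2, center, "+")
  emb <- rbind(blob(c(5, 0, 0, 0, 0), 60), blob(c(-5, 0, 0, 0, 0), 60))
  rownames(emb) <- sprintf("c%03d", 1:120)
  lab <- cluster_cells(emb, resolution = 0.5, n_neighbors = 10, seed = 0)
  expect_identical(length(unique(lab$cluster)), 2L)
  truth <- rep(c("a", "b"), each = 60)
  expect_equal(mclust::adjustedRandIndex(lab$cluster, truth), 1)
  # determinism under a fixed seed
  lab2 <- cluster_cells(emb, resolution = 0.5, n_neighbors = 10, seed = 0)
  expect_identical(lab$cluster, lab2$cluster)
  # identical cells collapse to one cluster
  same <- matrix(1, 30, 4)
  rownames(same) <- sprintf("s%02d", 1:30)
  expect_identical(unique(cluster_cells(same, n_neighbors = 5,
                                        seed = 1)$cluster), "1")
  expect_error(cluster_cells(emb, n_neighbors = 500), "n_neighbors")
})

test_that("subclustering reuses the parent embedding and recovers planted substates", {
  set.seed(43)
  blob <- function(center, n) sweep(matrix(rnorm(n * 4, 0, 0.15), n, 4),
                                    2, center, "+")
  # one distant cluster plus a parent made of three nearby substates
  emb <- rbind(blob(c(30, 0, 0, 0), 50),
               blob(c(0, 0, 0, 0), 40), blob(c(0, 3, 0, 0), 40),
               blob(c(0, 0, 3, 0), 40))
  rownames(emb) <- sprintf("c%03d", seq_len(nrow(emb)))
  labels <- structure(
    data.frame(cell = rownames(emb),
               cluster = rep(c("far", "P", "P", "P"),
                             c(50, 40, 40, 40))),
    class = c("cluster_labels", "data.frame"))
  sub <- subcluster(emb, labels, "P", resolution = 0.83,
                    n_neighbors = 10, seed = 0)
  # only parent cells are relabeled
  expect_setequal(sub$cell, rownames(emb)[51:170])
  expect_identical(length(unique(sub$cluster)), 3L)
  truth <- rep(1:3, each = 40)
  expect_equal(mclust::adjustedRandIndex(sub$cluster, truth), 1)
  expect_true(all(startsWith(sub$cluster, "P.")))
  expect_identical(attr(sub, "parent"), "P")
  expect_error(subcluster(emb, labels, "missing"), "not found")
  expect_error(subcluster(emb, labels, "far", n_neighbors = 100),
               "too few")
})

test_that("hvg selection prefers genes with planted extra variability", {
  set.seed(47)
  n <- 150
  flat <- matrix(rpois(n * 40, 5), n, 40)
  # lognormal rate with the same mean as the flat genes, so the extra
  # variability (not abundance) is what distinguishes them
  noisy <- sapply(1:10, function(j)
    rpois(n, exp(log(5) + rnorm(n, 0, 1) - 0.5)))
  ds <- raw_dataset(cbind(flat, noisy),
                    gene_ids = c(sprintf("flat%02d", 1:40),
                                 sprintf("noisy%02d", 1:10)))
  hv <- find_hvgs(normalize_log(ds), 10)
  expect_gte(sum(startsWith(hv, "noisy")), 8)
})
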