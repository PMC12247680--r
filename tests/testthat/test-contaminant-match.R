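test_that("centroids equal independently computed per-cluster means", {
  set.seed(61)
  m <- matrix(rpois(30 * 6, 5) + 1, 30, 6)
  ds <- normalize_log(raw_dataset(m, gene_ids = sprintf("g%d", 1:6)))
  labels <- data.frame(cell = ds$cell_meta$cell,
                       cluster = rep(c("x", "y", "z"), each = 10))
  cm <- cluster_centroids(ds, labels)
  y <- as.matrix(ds$matrix)
  for (cc in c("x", "y", "z"))
    expect_equal(unname(cm$centroids[cc, ]),
                 unname(colMeans(y[labels$cluster == cc, ])))
  # single-cell and duplicated-cell clusters
  one <- cluster_centroids(ds, labels[1, , drop = FALSE])
  expect_equal(unname(one$centroids[1, ]), unname(y[1, ]))
  two <- cluster_centroids(ds, data.frame(cell = ds$cell_meta$cell[c(1, 1)],
                                          cluster = "dup"))
  expect_equal(unname(two$centroids[1, ]), unname(y[1, ]))
  expect_error(cluster_centroids(ds, labels, genes = c("g1", "nope")),
               "absent")
})

test_that("pair correlations match hand and brute-force Pearson", {
  a <- toy_centroids(rbind(c(1, 2, 3)))
  b <- toy_centroids(rbind(c(2, 4, 6), c(1, 3, 2), c(3, 2, 1)))
  r <- pair_correlations(a, b)
  expect_equal(unname(r[1, ]), c(1, 0.5, -1))
  # symmetry under argument swap, bounds, brute-force agreement
  for (s in 1:20) {
    set.seed(s)
    x <- toy_centroids(matrix(rnorm(5 * 12), 5, 12))
    y <- toy_centroids(matrix(rnorm(4 * 12), 4, 12))
    colnames(y$centroids) <- colnames(x$centroids)
    rxy <- pair_correlations(x, y)
    expect_equal(rxy, t(pair_correlations(y, x)))
    expect_true(all(rxy >= -1 - 1e-12 & rxy <= 1 + 1e-12))
    for (i in 1:5) for (j in 1:4)
      expect_equal(rxy[i, j], cor(x$centroids[i, ], y$centroids[j, ]))
  }
  # zero-variance centroid flagged and excluded
  z <- toy_centroids(rbind(c(2, 2, 2), c(1, 2, 3)))
  expect_warning(rz <- pair_correlations(z, b), "zero-variance")
  expect_true(all(is.na(rz[1, ])))
  expect_false(anyNA(rz[2, ]))
})

test_that("marker overlap score is the top-k Jaccard", {
  slice <- function(genes) data.frame(cluster = "c", gene = genes,
                                      rank = seq_along(genes))
  a <- slice(sprintf("g%02d", 1:20))
  expect_equal(marker_overlap_score(a, a, 20), 1)
  b <- slice(sprintf("h%02d", 1:20))
  expect_equal(marker_overlap_score(a, b, 20), 0)
  # 5 shared of top 20 each (union 35)
  c5 <- slice(c(sprintf("g%02d", 1:5), sprintf("h%02d", 1:15)))
  expect_equal(marker_overlap_score(a, c5, 20), 5 / 35)
  expect_error(marker_overlap_score(a, b, 50), "top_k")
})

test_that("replicate calibration brackets the planted correlation levels", {
  # no rare-mimic state here: a 4-cell state split across replicates has
  # no measurable replicate centroid and the bracket property presumes
  # states represented in both replicates
  pair <- make_expression_pair(small_pair_spec(71, rare_mimic = NULL))
  b <- normalize_log(pair$blood)
  lab <- true_state_labels(b)
  rep1 <- b$cell_meta$replicate == "rep1"
  r1 <- list(ds = b, labels = lab[rep1, ])
  r2 <- list(ds = b, labels = lab[!rep1, ])
  thr <- calibrate_threshold(r1, r2, b$gene_ids)
  expect_false(attr(thr, "calibration_failed"))
  rr <- attr(thr, "coverage_correlations")
  shared_states <- intersect(rownames(rr), colnames(rr))
  within <- vapply(shared_states, function(s) rr[s, s], numeric(1))
  cross <- rr[outer(rownames(rr), colnames(rr), "!=")]
  expect_gt(as.numeric(thr), max(cross))
  expect_lte(as.numeric(thr), min(within))
  # identical replicates calibrate to the grid cap
  same <- calibrate_threshold(r1, r1, b$gene_ids)
  expect_equal(as.numeric(same), 0.99)
  # relabeling clusters and duplicating every cell change nothing
  perm <- r1$labels
  perm$cluster <- paste0("cl_", perm$cluster)
  dup1 <- list(ds = r1$ds, labels = rbind(r1$labels, r1$labels))
  expect_equal(as.numeric(calibrate_threshold(
    list(ds = b, labels = perm), r2, b$gene_ids)), as.numeric(thr))
  expect_equal(as.numeric(calibrate_threshold(dup1, r2, b$gene_ids)),
               as.numeric(thr))
})

test_that("calibration falls back to 0.5 when coverage is impossible", {
  # anti-correlated states: no grid value achieves bipartite coverage
  x <- expression_dataset(rbind(c(0, 1, 2, 3), c(0.1, 1, 2, 3.2)),
                          stage = "normalized",
                          gene_ids = sprintf("g%d", 1:4))
  y <- expression_dataset(rbind(c(3, 2, 1, 0), c(3.2, 2, 1, 0.1)),
                          stage = "normalized",
                          gene_ids = sprintf("g%d", 1:4))
  lx <- data.frame(cell = x$cell_meta$cell, cluster = "qx")
  ly <- data.frame(cell = y$cell_meta$cell, cluster = "qy")
  thr2 <- calibrate_threshold(list(ds = x, labels = lx),
                              list(ds = y, labels = ly), x$gene_ids)
  expect_equal(as.numeric(thr2), 0.5)
  expect_true(attr(thr2, "calibration_failed"))
})

test_that("verdict rules reproduce the published worked cases", {
  cfg <- match_config()
  # near-threshold pair at r = 0.494 rescued by marker overlap
  r <- matrix(c(0.494, 0.1), 1, 2,
              dimnames = list("q6", c("b10", "b2")))
  frac_q <- c(q6 = 0.05)
  frac_r <- c(b10 = 0.4, b2 = 0.6)
  v <- heartgrowth:::.match_verdicts(r, frac_q, frac_r, cfg,
                                     function(qc, ref) 0.6)
  expect_identical(v$verdict, "contaminant")
  expect_identical(v$provenance, "margin_rescued")
  # the same pair with weak marker overlap stays retained
  v2 <- heartgrowth:::.match_verdicts(r, frac_q, frac_r, cfg,
                                      function(qc, ref) 0.05)
  expect_identical(v2$verdict, "retained")
  expect_identical(v2$provenance, "below")
  # rare reference state (0.17% of cells) vs abundant query (12.1%):
  # match suppressed despite r above threshold
  r3 <- matrix(0.8, 1, 1, dimnames = list("q1", "c31"))
  v3 <- heartgrowth:::.match_verdicts(r3, c(q1 = 0.121), c(c31 = 0.0017),
                                      cfg, function(qc, ref) 1)
  expect_identical(v3$verdict, "retained")
  expect_identical(v3$provenance, "abundance_suppressed")
  # nothing near the threshold: all clusters retained as 'below'
  r4 <- matrix(c(0.2, -0.3), 2, 1,
               dimnames = list(c("qa", "qb"), "ref"))
  v4 <- heartgrowth:::.match_verdicts(r4, c(qa = 0.5, qb = 0.5),
                                      c(ref = 1), cfg,
                                      function(qc, ref) 1)
  expect_identical(unique(v4$verdict), "retained")
  expect_identical(unique(v4$provenance), "below")
})

test_that("matching on planted data is perfectly sensitive and specific", {
  pair <- make_expression_pair(expression_sim_spec(seed = 42))
  h <- normalize_log(pair$heart); b <- normalize_log(pair$blood)
  lh <- true_state_labels(h); lb <- true_state_labels(b)
  mh <- rank_markers(h, lh); mb <- rank_markers(b, lb)
  res <- match_contaminants(list(ds = h, labels = lh),
                            list(ds = b, labels = lb),
                            h$gene_ids, match_config(), mh, mb)
  v <- merge(res$verdicts, pair$truth,
             by.x = "query_cluster", by.y = "heart_state")
  expect_true(all(v$verdict[v$true_contaminant] == "contaminant"))
  expect_true(all(v$verdict[!v$true_contaminant] == "retained"))
  # the planted margin pair is rescued, the rare mimic suppressed
  expect_identical(v$provenance[v$planted == "margin_rescue"],
                   "margin_rescued")
  expect_identical(v$provenance[v$planted == "rare_mimic_target"],
                   "abundance_suppressed")
  # every query cluster received exactly one verdict
  expect_setequal(res$verdicts$query_cluster, pair$truth$heart_state)
  expect_identical(anyDuplicated(res$verdicts$query_cluster), 0L)
  # disabling the abundance guard can only add contaminant labels
  res0 <- match_contaminants(list(ds = h, labels = lh),
                             list(ds = b, labels = lb), h$gene_ids,
                             match_config(abundance_ratio_min = 0),
                             mh, mb)
  was <- res$verdicts$query_cluster[res$verdicts$verdict == "contaminant"]
  now <- res0$verdicts$query_cluster[res0$verdicts$verdict ==
                                       "contaminant"]
  expect_true(all(was %in% now))
  expect_error(match_contaminants(list(ds = h, labels = lh),
                                  list(ds = b, labels = lb),
                                  h$gene_ids, match_config(margin = 0.02)),
               "marker tables")
})
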