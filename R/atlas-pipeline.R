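#' Filter cells by detected-gene count
#'
#' Removes cells expressing fewer than `min_genes` genes (strict
#' less-than: a cell detecting exactly `min_genes` genes is retained).
#' Adds the QC metrics `n_genes_detected` and `total_counts` to the cell
#' metadata; these later serve as the default technical covariates of
#' [regress_and_scale()].
#'
#' @param ds An [expression_dataset] at stage `"raw"`.
#' @param min_genes Minimum number of detected genes (default 400).
#' @return The filtered raw dataset.
#' @export
qc_filter <- function(ds, min_genes = 400) {
  .check_stage(ds, "raw", "qc_filter")
  m <- ds$matrix
  detected <- if (inherits(m, "sparseMatrix"))
    Matrix::rowSums(m > 0) else rowSums(m > 0)
  totals <- if (inherits(m, "sparseMatrix"))
    Matrix::rowSums(m) else rowSums(m)
  keep <- detected >= min_genes
  meta <- ds$cell_meta[keep, , drop = FALSE]
  meta$n_genes_detected <- as.numeric(detected[keep])
  meta$total_counts <- as.numeric(totals[keep])
  expression_dataset(m[keep, , drop = FALSE], gene_ids = ds$gene_ids,
                     cell_meta = meta, stage = "raw")
}

#' Depth-normalize and log-transform
#'
#' Scales each cell to a common target sum (1e4 by default) and applies
#' the natural `log(1 + x)` transform. After the transform, the per-cell
#' sum of `expm1()` over all genes equals the target sum.
#'
#' @param ds An [expression_dataset] at stage `"raw"`.
#' @param target_sum Per-cell target total (default `1e4`).
#' @return The dataset at stage `"normalized"`.
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  .check_stage(ds, "raw", "normalize_log")
  m <- ds$matrix
  totals <- if (inherits(m, "sparseMatrix"))
    Matrix::rowSums(m) else rowSums(m)
  if (any(totals == 0)) {
    bad <- ds$cell_meta$cell[which(totals == 0)[1L]]
    stop("cell '", bad, "' has zero total counts and cannot be ",
         "normalized; filter it out first", call. = FALSE)
  }
  meta <- ds$cell_meta
  if (is.null(meta$total_counts)) meta$total_counts <- as.numeric(totals)
  if (is.null(meta$n_genes_detected))
    meta$n_genes_detected <- as.numeric(
      if (inherits(m, "sparseMatrix")) Matrix::rowSums(m > 0) else
        rowSums(m > 0))
  if (inherits(m, "sparseMatrix")) {
    norm <- Matrix::Diagonal(x = target_sum / totals) %*% m
    norm <- methods::as(norm, "CsparseMatrix")
    norm@x <- log1p(norm@x)
  } else {
    norm <- log1p(m * (target_sum / totals))
  }
  expression_dataset(norm, gene_ids = ds$gene_ids, cell_meta = meta,
                     stage = "normalized")
}

#' Regress out technical covariates and scale genes
#'
#' Fits, per gene, an ordinary least-squares regression of the
#' normalized values on the named technical covariates (total counts
#' and detected genes by default, mirroring the usual nuisance metrics)
#' and keeps the residuals; each gene is then standardized to unit
#' variance and values above `max_value` are clipped. Genes with zero
#' residual variance become all-zero.
#'
#' @param ds An [expression_dataset] at stage `"normalized"`.
#' @param covariates Character vector of `cell_meta` column names to
#'   regress out; use `character()` to skip regression and only scale.
#' @param max_value Upper clip applied after standardization.
#' @return The dataset at stage `"scaled"` (dense matrix).
#' @export
regress_and_scale <- function(ds,
                              covariates = c("total_counts",
                                             "n_genes_detected"),
                              max_value = 10) {
  .check_stage(ds, "normalized", "regress_and_scale")
  y <- as.matrix(ds$matrix)
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, colnames(ds$cell_meta))
    if (length(missing_cov))
      stop("covariate(s) missing from cell_meta: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    x <- cbind(`(Intercept)` = 1,
               scale(as.matrix(ds$cell_meta[, covariates, drop = FALSE])))
    x[is.nan(x)] <- 0  # constant covariate
    fit <- stats::lm.fit(x, y)
    y <- as.matrix(fit$residuals)
  } else {
    y <- sweep(y, 2L, colMeans(y))
  }
  sds <- sqrt(colSums(y^2) / max(1, nrow(y) - 1L))
  nz <- sds > 1e-12
  y[, nz] <- sweep(y[, nz, drop = FALSE], 2L, sds[nz], "/")
  y[, !nz] <- 0
  y[y > max_value] <- max_value
  expression_dataset(y, gene_ids = ds$gene_ids, cell_meta = ds$cell_meta,
                     stage = "scaled")
}

#' Principal component analysis with elbow-based dimensionality choice
#'
#' Computes a truncated PCA of the scaled matrix and chooses the number
#' of informative components from the log variance-ratio curve: the
#' elbow is formalized as the largest component index `k` such that the
#' drop in log variance ratio from `k` to `k + 1` is at least
#' `elbow_frac` of the total log-range across the computed components.
#'
#' @param ds An [expression_dataset] at stage `"scaled"`.
#' @param n_components Number of components to compute.
#' @param elbow_frac Fraction of the total log variance-ratio range that
#'   a consecutive drop must exceed to count as informative (default
#'   0.05).
#' @return An object of class `pca_embedding`: list with `embedding`
#'   (cells x `n_components` scores), `variance_ratio` (nonincreasing),
#'   `n_informative`, and `rotation`.
#' @export
run_pca <- function(ds, n_components = 50, elbow_frac = 0.05) {
  .check_stage(ds, "scaled", "run_pca")
  y <- as.matrix(ds$matrix)
  if (n_components >= nrow(y))
    stop("'n_components' must be smaller than the number of cells",
         call. = FALSE)
  n_components <- min(n_components, ncol(y))
  pc <- stats::prcomp(y, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  vr_k <- vr[seq_len(n_components)]
  lv <- log(pmax(vr_k, 1e-300))
  rng <- lv[1L] - lv[length(lv)]
  n_inf <- if (rng <= 0) 1L else {
    drops <- -diff(lv)
    big <- which(drops >= elbow_frac * rng)
    if (length(big)) max(big) else length(lv)
  }
  emb <- pc$x
  rownames(emb) <- ds$cell_meta$cell
  structure(list(embedding = emb, variance_ratio = vr_k,
                 n_informative = n_inf, rotation = pc$rotation),
            class = "pca_embedding")
}

#' Highly variable genes by normalized dispersion
#'
#' Ranks genes by the dispersion (variance/mean of the de-logged
#' normalized expression) standardized within 20 mean-expression bins,
#' and returns the top `n`.
#'
#' @param ds An [expression_dataset] at stage `"normalized"`.
#' @param n Number of genes to return (capped at the number of expressed
#'   genes).
#' @return Character vector of gene ids.
#' @export
find_hvgs <- function(ds, n = 2000) {
  .check_stage(ds, "normalized", "find_hvgs")
  e <- expm1(as.matrix(ds$matrix))
  mu <- colMeans(e)
  v <- apply(e, 2L, stats::var)
  ok <- mu > 0
  disp <- v[ok] / mu[ok]
  n_bins <- min(20L, max(1L, sum(ok) %/% 10L))
  bins <- cut(rank(mu[ok], ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- stats::sd(disp[sel])
    z[sel] <- if (is.na(s) || s < 1e-12) 0 else
      (disp[sel] - mean(disp[sel])) / s
  }
  genes <- names(sort(z, decreasing = TRUE))
  utils::head(genes, min(n, length(genes)))
}

#' Louvain clustering on a k-nearest-neighbor graph
#'
#' Builds an (unweighted, undirected) k-nearest-neighbor graph on the
#' PCA embedding and partitions it with Louvain community detection at
#' the given resolution under a fixed seed. If all cells are identical
#' in the embedding, a single cluster is returned.
#'
#' @param embedding A `pca_embedding` from [run_pca()] or a numeric
#'   matrix of cell coordinates (rownames = cell ids). When a
#'   `pca_embedding` is given, only its informative components are used.
#' @param resolution Louvain resolution parameter.
#' @param n_neighbors Neighbors per cell; must be smaller than the
#'   number of cells.
#' @param seed RNG seed fixed for the community detection.
#' @return An object of class `cluster_labels`: a data frame with
#'   columns `cell` and `cluster` (character), with attributes
#'   `resolution`, `n_neighbors`, `seed` and `parent` (`NA` for a
#'   top-level clustering).
#' @export
cluster_cells <- function(embedding, resolution = 1.0, n_neighbors = 15,
                          seed = 0) {
  emb <- if (inherits(embedding, "pca_embedding"))
    embedding$embedding[, seq_len(embedding$n_informative), drop = FALSE]
  else as.matrix(embedding)
  n <- nrow(emb)
  if (n_neighbors >= n)
    stop("'n_neighbors' must be smaller than the number of cells",
         call. = FALSE)
  cells <- rownames(emb)
  if (is.null(cells)) cells <- sprintf("cell%05d", seq_len(n))
  membership <- .louvain_knn(emb, n_neighbors, resolution, seed)
  out <- data.frame(cell = cells, cluster = as.character(membership),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cluster_labels", "data.frame"),
            resolution = resolution, n_neighbors = n_neighbors,
            seed = seed, parent = NA_character_)
}

.louvain_knn <- function(emb, n_neighbors, resolution, seed) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  if (max(d) < 1e-12) return(rep(1L, n))
  edges <- matrix(0L, n * n_neighbors, 2L)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1L)]
    edges[(i - 1L) * n_neighbors + seq_len(n_neighbors), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sub-cluster one parent cluster on the parent embedding
#'
#' Restricts the previously computed PCA coordinates to the cells of one
#' parent cluster (no re-PCA, preserving the parent structure), rebuilds
#' the neighbor graph on that subset and reruns Louvain at a fixed
#' resolution (0.83 by default). Cells outside the parent cluster are
#' untouched.
#'
#' @param embedding The parent `pca_embedding` (or coordinate matrix)
#'   used for the top-level clustering.
#' @param labels The parent [cluster_cells()] labels.
#' @param parent_cluster Cluster id to subdivide.
#' @param resolution Louvain resolution for the sub-clustering.
#' @param n_neighbors Neighbors per cell within the parent cluster.
#' @param seed RNG seed.
#' @return A `cluster_labels` object covering only the parent cells,
#'   with sub-cluster ids of the form `"<parent>.<k>"` and attribute
#'   `parent = parent_cluster`.
#' @export
subcluster <- function(embedding, labels, parent_cluster,
                       resolution = 0.83, n_neighbors = 15, seed = 0) {
  stopifnot(inherits(labels, "cluster_labels"))
  emb <- if (inherits(embedding, "pca_embedding"))
    embedding$embedding[, seq_len(embedding$n_informative), drop = FALSE]
  else as.matrix(embedding)
  sel <- labels$cluster == as.character(parent_cluster)
  if (!any(sel))
    stop("parent cluster '", parent_cluster, "' not found in labels",
         call. = FALSE)
  cells <- labels$cell[sel]
  sub <- emb[match(cells, rownames(emb)), , drop = FALSE]
  if (nrow(sub) < n_neighbors + 1L)
    stop("parent cluster has too few cells (", nrow(sub),
         ") for n_neighbors = ", n_neighbors, call. = FALSE)
  membership <- .louvain_knn(sub, n_neighbors, resolution, seed)
  out <- data.frame(cell = cells,
                    cluster = sprintf("%s.%d", parent_cluster, membership),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cluster_labels", "data.frame"),
            resolution = resolution, n_neighbors = n_neighbors,
            seed = seed, parent = as.character(parent_cluster))
}
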