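#' One-vs-rest Wilcoxon rank-sum marker ranking
#'
#' For each cluster and gene, tests whether the gene's normalized
#' expression in the cluster differs from all remaining cells with a
#' two-sided Wilcoxon rank-sum test. Exact p-values are used when both
#' group sizes are below 50 and the gene has no tied values (the usual
#' exactness conditions); otherwise a normal approximation with tie
#' correction. Benjamini-Hochberg adjustment is applied per cluster
#' across genes. Effect size is the log2 fold change of the de-logged
#' means; detection fractions inside and outside the cluster are
#' reported so that broadly expressed and specific low-expressed markers
#' can be distinguished.
#'
#' @param ds An [expression_dataset] at stage `"normalized"`.
#' @param labels A [cluster_cells()] labeling of the same cells (cells
#'   missing from `labels` are ignored).
#' @return A `marker_table` data frame with columns `cluster`, `gene`,
#'   `rank` (1 = most enriched, unique within cluster), `statistic`
#'   (rank-sum U of the cluster group), `z`, `logfc`, `p_value`,
#'   `p_adj`, `pct_in`, `pct_out`.
#' @export
rank_markers <- function(ds, labels) {
  .check_stage(ds, "normalized", "rank_markers")
  stopifnot(inherits(labels, "cluster_labels"))
  idx <- match(labels$cell, ds$cell_meta$cell)
  if (anyNA(idx))
    stop("labels contain cells absent from the dataset", call. = FALSE)
  y <- as.matrix(ds$matrix)[idx, , drop = FALSE]
  cl <- labels$cluster
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L)
    stop("marker ranking requires at least 2 clusters", call. = FALSE)
  n <- nrow(y)
  g <- ncol(y)
  ranks <- apply(y, 2L, rank)
  # per-gene tie term sum(t^3 - t) for the variance correction
  tie_term <- apply(y, 2L, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  has_ties <- tie_term > 0

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    sel <- cl == clusters[ci]
    n1 <- sum(sel); n2 <- n - n1
    r1 <- colSums(ranks[sel, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (u - mu) / sqrt(pmax(sig2, 1e-300))
    p <- 2 * stats::pnorm(-abs(z))
    exact_ok <- n1 < 50 && n2 < 50
    if (exact_ok && any(!has_ties)) {
      for (j in which(!has_ties)) {
        uj <- u[j]
        p[j] <- if (uj > n1 * n2 / 2)
          min(1, 2 * stats::pwilcox(uj - 1, n1, n2, lower.tail = FALSE))
        else min(1, 2 * stats::pwilcox(uj, n1, n2))
      }
    }
    m_in <- colMeans(expm1(y[sel, , drop = FALSE]))
    m_out <- colMeans(expm1(y[!sel, , drop = FALSE]))
    logfc <- log2((m_in + 1e-9) / (m_out + 1e-9))
    pct_in <- colMeans(y[sel, , drop = FALSE] > 0)
    pct_out <- colMeans(y[!sel, , drop = FALSE] > 0)
    # ties in z are common when genes separate a cluster completely;
    # break them by effect size so the strongest markers rank first
    ord <- order(-z, -logfc, ds$gene_ids)
    tab <- data.frame(cluster = clusters[ci], gene = ds$gene_ids,
                      rank = NA_integer_, statistic = u, z = z,
                      logfc = logfc, p_value = pmin(1, p),
                      p_adj = stats::p.adjust(pmin(1, p), "BH"),
                      pct_in = pct_in, pct_out = pct_out,
                      stringsAsFactors = FALSE)
    tab$rank[ord] <- seq_len(g)
    out[[ci]] <- tab[order(tab$rank), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top expressed genes per cluster
#'
#' Auxiliary list ranking genes by mean normalized expression within
#' each cluster.
#'
#' @param ds An [expression_dataset] at stage `"normalized"`.
#' @param labels A [cluster_cells()] labeling.
#' @param n Genes per cluster.
#' @return Data frame with columns `cluster`, `gene`, `mean_expr`.
#' @export
top_expressed_genes <- function(ds, labels, n = 20) {
  .check_stage(ds, "normalized", "top_expressed_genes")
  idx <- match(labels$cell, ds$cell_meta$cell)
  y <- as.matrix(ds$matrix)[idx, , drop = FALSE]
  out <- lapply(sort(unique(labels$cluster)), function(cc) {
    m <- colMeans(y[labels$cluster == cc, , drop = FALSE])
    ord <- utils::head(order(m, decreasing = TRUE), n)
    data.frame(cluster = cc, gene = ds$gene_ids[ord], mean_expr = m[ord],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specific low-expressed markers
#'
#' Filters a marker table for genes detected in most cells of their
#' cluster but rarely outside it, regardless of expression level.
#'
#' @param markers A `marker_table` from [rank_markers()].
#' @param min_pct_in Minimum in-cluster detection fraction.
#' @param max_pct_out Maximum out-of-cluster detection fraction.
#' @return The filtered marker table rows.
#' @export
specific_markers <- function(markers, min_pct_in = 0.5,
                             max_pct_out = 0.1) {
  stopifnot(inherits(markers, "marker_table"))
  markers[markers$pct_in >= min_pct_in & markers$pct_out <= max_pct_out,
          , drop = FALSE]
}
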