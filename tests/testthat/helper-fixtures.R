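# Fixture builders shared by the test files. Everything is generated in
# code; no data files.

# Construct a heart_state directly from a per-cell description, for
# oracle tests that need full control over schedules and labels.
make_test_heart <- function(df, day = 3) {
  n <- nrow(df)
  type <- match(df$type, c("distal_UL", "midline_UL", "precursor",
                           "myocyte"))
  cend <- if (is.null(df$cluster_end)) rep(0L, n) else
    match(df$cluster_end, c("none", "dorsal", "ventral")) - 1L
  cells <- list(
    heart = rep(1L, n),
    id = seq_len(n),
    type = as.integer(type),
    cluster_end = as.integer(cend),
    position = if (is.null(df$position)) rep(NA_real_, n) else
      as.numeric(df$position),
    birth_day = if (is.null(df$birth_day)) rep(day, n) else
      as.numeric(df$birth_day),
    labeled = if (is.null(df$labeled)) rep(FALSE, n) else
      as.logical(df$labeled),
    founder = if (is.null(df$founder)) rep(NA_integer_, n) else
      as.integer(df$founder),
    next_division = if (is.null(df$next_division)) rep(NA_real_, n) else
      as.numeric(df$next_division)
  )
  structure(list(day = day, cells = cells, next_id = n + 1L,
                 n_divisions = 0L, n_hearts = 1L),
            class = "heart_state")
}

# cluster_labels built from the generator's true states (for isolating
# stages downstream of clustering)
true_state_labels <- function(ds) {
  structure(data.frame(cell = ds$cell_meta$cell,
                       cluster = ds$cell_meta$true_state,
                       stringsAsFactors = FALSE),
            class = c("cluster_labels", "data.frame"),
            resolution = NA_real_, n_neighbors = NA_integer_,
            seed = NA_integer_, parent = NA_character_)
}

# a small expression pair spec that keeps unit tests fast
small_pair_spec <- function(seed, ...) {
  expression_sim_spec(n_genes = 300,
                      cells_per_state = c(mean = 40, dispersion = 0.1),
                      depth_range = c(800L, 1500L),
                      seed = seed, ...)
}

# raw expression_dataset from a dense count matrix
raw_dataset <- function(counts, ...) {
  expression_dataset(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                 "CsparseMatrix"), ...)
}

# centroid_matrix from an explicit matrix (for correlation-rule tests)
toy_centroids <- function(m, fractions = NULL, dataset = "toy") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  if (is.null(fractions)) fractions <- rep(1 / nrow(m), nrow(m))
  names(fractions) <- rownames(m)
  sizes <- stats::setNames(rep(10L, nrow(m)), rownames(m))
  structure(list(centroids = m, sizes = sizes, fractions = fractions,
                 dataset = dataset),
            class = "centroid_matrix")
}

# two-sided Fisher p by full enumeration of tables with fixed margins,
# independent of fisher.test
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[ks == a]
  sum(p[p <= obs * (1 + 1e-7)])
}
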