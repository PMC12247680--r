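#' Specification for a paired heart/blood synthetic expression dataset
#'
#' Describes a pair of single-cell count matrices ("heart" query and
#' "blood" reference) with planted ground truth, emulating the data
#' situation of a dissociated-heart dataset screened against a published
#' blood atlas: a small number of well-separated cell states per
#' dataset, of which some are genuinely shared (blood states present in
#' the heart), one optional pair is shared but only marginally similar
#' (exercising the near-threshold marker-overlap rescue), and one
#' optional rare reference state mimics an abundant query state
#' (exercising the abundance guard). Biological replicates are planted
#' as small shared log-mean shifts.
#'
#' Counts are Gamma-Poisson (negative binomial) around per-state
#' log-normal mean profiles, drawn conditionally on a fixed per-cell
#' library size, so per-cell totals always fall inside `depth_range`.
#' True state labels and replicate ids are always emitted in the cell
#' metadata; pipeline stages never consume them, they exist for
#' sensitivity/specificity scoring.
#'
#' @param n_genes Number of genes.
#' @param n_states_heart,n_states_blood Number of cell states per
#'   dataset.
#' @param cells_per_state Named vector `c(mean=, dispersion=)`: cells
#'   per state are drawn negative-binomially with this mean and
#'   dispersion (floored at 20).
#' @param profile_meanlog,profile_sdlog Location and scale of the
#'   log-normal per-state per-gene mean profiles.
#' @param shared_state_map Data frame with columns `heart`, `blood`:
#'   state indices planted as the same biological state (profiles copied
#'   from a common template). `NULL` for none.
#' @param rescue_pair `NULL`, or a list with elements `heart`, `blood`,
#'   `target_cor`, `n_markers`, `marker_strength`: a shared state whose
#'   heart profile is only partially correlated with its blood
#'   counterpart but shares a block of strong marker genes. The
#'   generator root-finds the profile mixing weight so that the
#'   realized centroid Pearson correlation of the pair equals
#'   `target_cor` (default 0.489, just below the default 0.5 match
#'   threshold) while the top-marker overlap remains high.
#' @param rare_mimic `NULL`, or a list with elements `heart`, `blood`,
#'   `n_cells`, `target_cells_factor`: a blood state restricted to
#'   `n_cells` cells whose profile copies an abundant heart-resident
#'   state (whose cell count is inflated by `target_cells_factor`) --
#'   transcriptomically similar but at a large abundance discrepancy.
#' @param nb_dispersion Negative-binomial overdispersion of counts.
#' @param depth_range Two integers: per-cell library-size range.
#' @param n_replicates Biological replicates per dataset.
#' @param replicate_shift_sd SD of the per-replicate per-gene log-mean
#'   shift shared by all cells of a replicate.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 1500,
                                n_states_heart = 6,
                                n_states_blood = 7,
                                cells_per_state = c(mean = 110,
                                                    dispersion = 0.08),
                                profile_meanlog = 0,
                                profile_sdlog = 1.2,
                                shared_state_map = data.frame(
                                  heart = c(5L, 6L), blood = c(5L, 6L)),
                                rescue_pair = list(heart = 4L, blood = 4L,
                                                   target_cor = 0.489,
                                                   n_markers = 25L,
                                                   marker_strength = 150),
                                rare_mimic = list(heart = 1L, blood = 7L,
                                                  n_cells = 4L,
                                                  target_cells_factor = 2),
                                nb_dispersion = 0.25,
                                depth_range = c(1500L, 4000L),
                                n_replicates = 2,
                                replicate_shift_sd = 0.08,
                                seed = NULL) {
  # tolerate JSON-derived configs: named lists for vectors, empty lists
  # for absent planted features
  if (is.list(cells_per_state)) cells_per_state <- unlist(cells_per_state)
  if (length(rescue_pair) == 0L) rescue_pair <- NULL
  if (length(rare_mimic) == 0L) rare_mimic <- NULL
  if (!is.null(shared_state_map) && !nrow(shared_state_map))
    shared_state_map <- NULL
  depth_range <- unlist(depth_range)
  spec <- list(n_genes = as.integer(n_genes),
               n_states_heart = as.integer(n_states_heart),
               n_states_blood = as.integer(n_states_blood),
               cells_per_state = cells_per_state,
               profile_meanlog = profile_meanlog,
               profile_sdlog = profile_sdlog,
               shared_state_map = shared_state_map,
               rescue_pair = rescue_pair,
               rare_mimic = rare_mimic,
               nb_dispersion = nb_dispersion,
               depth_range = as.integer(depth_range),
               n_replicates = as.integer(n_replicates),
               replicate_shift_sd = replicate_shift_sd,
               seed = seed)
  class(spec) <- "expression_sim_spec"
  validate_expression_sim_spec(spec)
  spec
}

validate_expression_sim_spec <- function(spec) {
  pos <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
  }
  pos(spec$n_genes, "n_genes")
  pos(spec$n_states_heart, "n_states_heart")
  pos(spec$n_states_blood, "n_states_blood")
  pos(spec$cells_per_state[["mean"]], "cells_per_state[mean]")
  pos(spec$cells_per_state[["dispersion"]], "cells_per_state[dispersion]")
  pos(spec$profile_sdlog, "profile_sdlog")
  pos(spec$nb_dispersion, "nb_dispersion")
  pos(spec$n_replicates, "n_replicates")
  if (spec$replicate_shift_sd < 0)
    stop("'replicate_shift_sd' must be nonnegative", call. = FALSE)
  if (length(spec$depth_range) != 2L || spec$depth_range[1] < 1 ||
      spec$depth_range[1] > spec$depth_range[2])
    stop("'depth_range' must be an increasing positive range",
         call. = FALSE)
  sm <- spec$shared_state_map
  if (!is.null(sm) && nrow(sm)) {
    if (any(sm$heart < 1 | sm$heart > spec$n_states_heart))
      stop("'shared_state_map' references invalid heart state ids",
           call. = FALSE)
    if (any(sm$blood < 1 | sm$blood > spec$n_states_blood))
      stop("'shared_state_map' references invalid blood state ids",
           call. = FALSE)
  }
  for (nm in c("rescue_pair", "rare_mimic")) {
    pr <- spec[[nm]]
    if (is.null(pr)) next
    if (pr$heart < 1 || pr$heart > spec$n_states_heart ||
        pr$blood < 1 || pr$blood > spec$n_states_blood)
      stop(sprintf("'%s' references invalid state ids", nm), call. = FALSE)
  }
  invisible(spec)
}

## sample a raw count matrix (cells x genes) for one dataset; returns the
## dataset plus the replicate shift matrix (needed when a planted state
## is recalibrated afterwards)
.sim_counts <- function(log_profiles, n_cells_per_state, spec, prefix) {
  G <- spec$n_genes
  S <- ncol(log_profiles)
  state <- rep(seq_len(S), n_cells_per_state)
  n <- length(state)
  replicate <- sample(rep_len(seq_len(spec$n_replicates), n))
  rep_shift <- matrix(stats::rnorm(G * spec$n_replicates, 0,
                                   spec$replicate_shift_sd),
                      G, spec$n_replicates)
  depth <- sample(seq(spec$depth_range[1], spec$depth_range[2]), n,
                  replace = TRUE)
  shape <- 1 / spec$nb_dispersion
  counts <- matrix(0L, n, G)
  for (i in seq_len(n)) {
    w <- exp(log_profiles[, state[i]] + rep_shift[, replicate[i]]) *
      stats::rgamma(G, shape = shape, rate = shape)
    counts[i, ] <- stats::rmultinom(1L, depth[i], w)
  }
  meta <- data.frame(
    cell = sprintf("%s_c%04d", prefix, seq_len(n)),
    dataset = prefix,
    replicate = sprintf("rep%d", replicate),
    true_state = sprintf("%s%d", toupper(substr(prefix, 1, 1)), state),
    stringsAsFactors = FALSE)
  ds <- expression_dataset(methods::as(Matrix::Matrix(counts,
                                                      sparse = TRUE),
                                       "CsparseMatrix"),
                           gene_ids = sprintf("gene%04d", seq_len(G)),
                           cell_meta = meta, stage = "raw")
  list(ds = ds, rep_shift = rep_shift, replicate = replicate)
}

#' Generate a paired heart/blood synthetic expression dataset
#'
#' Draws the pair of raw-count datasets described by an
#' [expression_sim_spec()], including the planted shared states,
#' marginal rescue pair and rare mimic state.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list with elements `heart` and `blood`
#'   ([expression_dataset] objects at stage `"raw"`, with `true_state`
#'   and `replicate` in `cell_meta`) and `truth`, a data frame scoring
#'   each heart state as truly contaminant (shared with blood) or
#'   heart-resident.
#' @examples
#' pair <- make_expression_pair(expression_sim_spec(
#'   n_genes = 200, cells_per_state = c(mean = 30, dispersion = 0.1),
#'   seed = 1))
#' pair$heart
#' @export
make_expression_pair <- function(spec) {
  validate_expression_sim_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  G <- spec$n_genes
  Sh <- spec$n_states_heart
  Sb <- spec$n_states_blood

  Lh <- matrix(stats::rnorm(G * Sh, spec$profile_meanlog,
                            spec$profile_sdlog), G, Sh)
  Lb <- matrix(stats::rnorm(G * Sb, spec$profile_meanlog,
                            spec$profile_sdlog), G, Sb)

  sm <- spec$shared_state_map
  if (!is.null(sm) && nrow(sm)) {
    for (k in seq_len(nrow(sm))) {
      tmpl <- stats::rnorm(G, spec$profile_meanlog, spec$profile_sdlog)
      Lh[, sm$heart[k]] <- tmpl
      Lb[, sm$blood[k]] <- tmpl
    }
  }

  rp <- spec$rescue_pair
  rescue <- NULL
  if (!is.null(rp)) {
    # both profiles carry the same boosted marker block; the heart
    # profile is a mix of the blood profile's standardized direction and
    # its own orthogonalized remainder (the marker elevation survives
    # through both components). The mixing weight is root-found below so
    # that the realized centroid correlation equals target_cor.
    mk <- sample.int(G, rp$n_markers)
    boost <- log(rp$marker_strength)
    v <- stats::rnorm(G, spec$profile_meanlog, spec$profile_sdlog)
    v[mk] <- v[mk] + boost
    u_raw <- stats::rnorm(G, spec$profile_meanlog, spec$profile_sdlog)
    u_raw[mk] <- u_raw[mk] + boost
    vc <- as.numeric(scale(v))
    u_perp <- as.numeric(scale(stats::residuals(stats::lm(u_raw ~ v))))
    mixprof <- function(mix) spec$profile_meanlog + stats::sd(v) *
      (mix * vc + sqrt(1 - mix^2) * u_perp)
    Lb[, rp$blood] <- v
    Lh[, rp$heart] <- mixprof(rp$target_cor)
    rescue <- list(mixprof = mixprof)
  }

  mm <- spec$rare_mimic
  if (!is.null(mm)) Lb[, mm$blood] <- Lh[, mm$heart]

  draw_n <- function(S) {
    n <- stats::rnbinom(S, mu = spec$cells_per_state[["mean"]],
                        size = 1 / spec$cells_per_state[["dispersion"]])
    pmax(20L, n)
  }
  nh <- draw_n(Sh)
  nb <- draw_n(Sb)
  if (!is.null(mm)) {
    nb[mm$blood] <- mm$n_cells
    # the mimicked query state is planted as clearly abundant, so the
    # abundance discrepancy with the rare reference state is large
    fac <- if (is.null(mm$target_cells_factor)) 2 else
      mm$target_cells_factor
    nh[mm$heart] <- as.integer(round(nh[mm$heart] * fac))
  }

  blood_sim <- .sim_counts(Lb, nb, spec, "blood")
  heart_sim <- .sim_counts(Lh, nh, spec, "heart")
  blood <- blood_sim$ds
  heart <- heart_sim$ds
  if (!is.null(rp))
    heart <- .calibrate_rescue(heart, blood, heart_sim, rescue$mixprof,
                               rp, spec)

  contam <- rep(FALSE, Sh)
  if (!is.null(sm) && nrow(sm)) contam[sm$heart] <- TRUE
  if (!is.null(rp)) contam[rp$heart] <- TRUE
  truth <- data.frame(
    heart_state = sprintf("H%d", seq_len(Sh)),
    true_contaminant = contam,
    planted = ifelse(seq_len(Sh) %in% (if (is.null(rp)) integer() else
      rp$heart), "margin_rescue",
      ifelse(seq_len(Sh) %in% (if (is.null(mm)) integer() else mm$heart),
             "rare_mimic_target",
             ifelse(contam, "shared", "heart_only"))),
    stringsAsFactors = FALSE)
  list(heart = heart, blood = blood, truth = truth)
}

## Regenerate the planted rescue state's heart cells, root-finding the
## profile mixing weight so that the realized centroid Pearson
## correlation with the blood partner equals target_cor. RNG draws are
## replayed from a snapshot at every trial weight, making the bisection
## a deterministic function of the seed.
.calibrate_rescue <- function(heart, blood, heart_sim, mixprof, rp,
                              spec) {
  G <- spec$n_genes
  bsel <- blood$cell_meta$true_state == sprintf("B%d", rp$blood)
  bm <- as.matrix(blood$matrix[bsel, , drop = FALSE])
  bc <- colMeans(log1p(bm / rowSums(bm) * 1e4))
  hsel <- which(heart$cell_meta$true_state == sprintf("H%d", rp$heart))
  depth <- as.numeric(Matrix::rowSums(heart$matrix[hsel, , drop = FALSE]))
  repid <- heart_sim$replicate[hsel]
  shape <- 1 / spec$nb_dispersion
  snap <- .Random.seed_save()
  gen <- function(mix) {
    .Random.seed_restore(snap)
    u <- mixprof(mix)
    cnt <- matrix(0L, length(hsel), G)
    for (i in seq_along(hsel)) {
      w <- exp(u + heart_sim$rep_shift[, repid[i]]) *
        stats::rgamma(G, shape = shape, rate = shape)
      cnt[i, ] <- stats::rmultinom(1L, depth[i], w)
    }
    cnt
  }
  fr <- function(mix) {
    cnt <- gen(mix)
    cc <- colMeans(log1p(cnt / rowSums(cnt) * 1e4))
    stats::cor(cc, bc) - rp$target_cor
  }
  lo <- 0.05; hi <- 0.95
  mix <- if (fr(lo) >= 0) lo else if (fr(hi) <= 0) hi else {
    for (it in 1:14) {
      mid <- (lo + hi) / 2
      if (fr(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  final <- gen(mix)
  m <- as.matrix(heart$matrix)
  m[hsel, ] <- final
  expression_dataset(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                 "CsparseMatrix"),
                     gene_ids = heart$gene_ids,
                     cell_meta = heart$cell_meta, stage = "raw")
}

#' Simulate a cohort of juvenile hearts at a given age
#'
#' Initializes `n_hearts` day-3 hearts under `params` and advances them
#' to `day` with the lineage simulator.
#'
#' @param params A [lineage_params()] object.
#' @param n_hearts Cohort size (0 yields an empty list).
#' @param day Target age in days; must be >= 3.
#' @return A list of `n_hearts` independent `heart_state` objects at
#'   `day`.
#' @examples
#' set.seed(1)
#' cohort <- make_heart_cohort(lineage_params(), 5, 3)
#' length(cohort)
#' @export
make_heart_cohort <- function(params, n_hearts, day = 3) {
  validate_lineage_params(params)
  if (!is.numeric(day) || day < 3)
    stop("'day' must be >= 3 (hearts initialize at day 3)", call. = FALSE)
  n_hearts <- as.integer(n_hearts)
  if (n_hearts == 0L) return(list())
  state <- init_heart(params, n_hearts)
  n_steps <- as.integer(round((day - 3) / DT_INTERNAL))
  for (i in seq_len(n_steps))
    state <- .step_cells(state, params, DT_INTERNAL)
  .split_hearts(state)
}
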