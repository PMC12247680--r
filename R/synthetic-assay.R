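#' Specification for synthetic perturbation assay tables
#'
#' Describes multi-trial drug or crispant assays on juvenile hearts as
#' generated count tables: per-animal midline UL counts, per-region
#' nucleus and EdU+ counts, binary morphology scores and pre/post heart
#' rates, with per-condition multiplicative effects. Every trial
#' contains a control arm (`"DMSO"` by default).
#'
#' @param n_trials Number of independent trials.
#' @param animals_per_arm Animals per condition per trial (> 0).
#' @param conditions Character vector of condition labels; must include
#'   `control_condition`.
#' @param control_condition Label of the control arm.
#' @param baseline_midline_ul Named vector `c(mean=, dispersion=)` for
#'   the negative-binomial midline UL count of a control animal.
#' @param regions Anatomical regions scored for EdU.
#' @param nuclei_per_region Expected nuclei counted per region (Poisson
#'   mean).
#' @param edu_rate Named per-region baseline probability that a nucleus
#'   is EdU+.
#' @param effect_multipliers Named list: condition -> named numeric of
#'   multiplicative effects. Names may be region names (scaling that
#'   region's EdU rate) or `"midline_ul"` (scaling the UL count mean).
#'   Conditions absent from the list have all multipliers 1.
#' @param abnormal_prob Named per-condition probability that a heart is
#'   scored morphologically abnormal.
#' @param heart_rate_mean,heart_rate_sd Baseline beats-per-minute
#'   distribution.
#' @param heart_rate_shift Named per-condition additive shift of the
#'   post-treatment heart rate.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(n_trials = 3,
                           animals_per_arm = 16,
                           conditions = c("DMSO", "aprepitant"),
                           control_condition = "DMSO",
                           baseline_midline_ul = c(mean = 12,
                                                   dispersion = 0.05),
                           regions = c("dorsal", "midline", "ventral"),
                           nuclei_per_region = 40,
                           edu_rate = c(dorsal = 0.12, midline = 0.05,
                                        ventral = 0.12),
                           effect_multipliers = list(
                             aprepitant = c(dorsal = 0.4, ventral = 0.4)),
                           abnormal_prob = c(DMSO = 0.03,
                                             aprepitant = 0.03),
                           heart_rate_mean = 38,
                           heart_rate_sd = 4,
                           heart_rate_shift = c(DMSO = 0,
                                                aprepitant = -6),
                           seed = NULL) {
  # tolerate JSON-derived configs (named lists in place of vectors)
  if (is.list(baseline_midline_ul))
    baseline_midline_ul <- unlist(baseline_midline_ul)
  if (is.list(edu_rate)) edu_rate <- unlist(edu_rate)
  if (is.list(abnormal_prob)) abnormal_prob <- unlist(abnormal_prob)
  if (is.list(heart_rate_shift)) heart_rate_shift <- unlist(heart_rate_shift)
  conditions <- unlist(conditions)
  regions <- unlist(regions)
  effect_multipliers <- lapply(effect_multipliers, unlist)
  spec <- list(n_trials = as.integer(n_trials),
               animals_per_arm = as.integer(animals_per_arm),
               conditions = conditions,
               control_condition = control_condition,
               baseline_midline_ul = baseline_midline_ul,
               regions = regions,
               nuclei_per_region = nuclei_per_region,
               edu_rate = edu_rate,
               effect_multipliers = effect_multipliers,
               abnormal_prob = abnormal_prob,
               heart_rate_mean = heart_rate_mean,
               heart_rate_sd = heart_rate_sd,
               heart_rate_shift = heart_rate_shift,
               seed = seed)
  class(spec) <- "assay_sim_spec"
  validate_assay_sim_spec(spec)
  spec
}

validate_assay_sim_spec <- function(spec) {
  if (spec$animals_per_arm < 1)
    stop("'animals_per_arm' must be at least 1", call. = FALSE)
  if (spec$n_trials < 1)
    stop("'n_trials' must be at least 1", call. = FALSE)
  if (!spec$control_condition %in% spec$conditions)
    stop("'conditions' must include the control condition '",
         spec$control_condition, "'", call. = FALSE)
  if (any(spec$abnormal_prob < 0 | spec$abnormal_prob > 1))
    stop("'abnormal_prob' entries must be probabilities in [0, 1]",
         call. = FALSE)
  if (any(spec$edu_rate < 0 | spec$edu_rate > 1))
    stop("'edu_rate' entries must be probabilities in [0, 1]",
         call. = FALSE)
  for (cond in names(spec$effect_multipliers))
    if (any(spec$effect_multipliers[[cond]] < 0))
      stop("effect multipliers must be nonnegative (condition '",
           cond, "')", call. = FALSE)
  invisible(spec)
}

.mult_for <- function(spec, condition, what) {
  m <- spec$effect_multipliers[[condition]]
  if (is.null(m) || is.na(m[what]) || !what %in% names(m)) 1 else
    unname(m[what])
}

#' Generate a long-format synthetic assay table
#'
#' Draws the per-animal measurements described by an
#' [assay_sim_spec()]: one row per animal per measured quantity, in the
#' long schema `trial, condition, animal, region, measure, value`
#' consumed by the assay statistics (see [normalized_ul_counts()],
#' [percent_edu()], [crispant_morphology_test()], [paired_rate_test()]).
#'
#' @param spec An [assay_sim_spec()].
#' @return A data frame (`assay_table`) with columns `trial`,
#'   `condition`, `animal`, `region`, `measure`, `value`. Region is
#'   `"none"` for whole-animal measures (`midline_ul_count`, `abnormal`,
#'   `heart_rate_pre`, `heart_rate_post`).
#' @examples
#' tab <- make_assay_tables(assay_sim_spec(seed = 1))
#' head(tab)
#' @export
make_assay_tables <- function(spec) {
  validate_assay_sim_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- list()
  k <- 0L
  add <- function(trial, condition, animal, region, measure, value) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(trial = trial, condition = condition,
                             animal = animal, region = region,
                             measure = measure, value = value,
                             stringsAsFactors = FALSE)
  }
  disp <- spec$baseline_midline_ul[["dispersion"]]
  for (t in seq_len(spec$n_trials)) {
    trial <- sprintf("trial%d", t)
    for (cond in spec$conditions) {
      for (a in seq_len(spec$animals_per_arm)) {
        animal <- sprintf("%s_%s_a%02d", trial, cond, a)
        mu_ul <- spec$baseline_midline_ul[["mean"]] *
          .mult_for(spec, cond, "midline_ul")
        add(trial, cond, animal, "none", "midline_ul_count",
            stats::rnbinom(1, mu = mu_ul, size = 1 / disp))
        for (rg in spec$regions) {
          ntot <- stats::rpois(1, spec$nuclei_per_region)
          rate <- min(1, spec$edu_rate[[rg]] * .mult_for(spec, cond, rg))
          add(trial, cond, animal, rg, "nuclei_total", ntot)
          add(trial, cond, animal, rg, "edu_pos",
              stats::rbinom(1, ntot, rate))
        }
        pab <- spec$abnormal_prob[[cond]]
        if (is.null(pab)) pab <- 0
        add(trial, cond, animal, "none", "abnormal",
            stats::rbinom(1, 1, pab))
        pre <- stats::rnorm(1, spec$heart_rate_mean, spec$heart_rate_sd)
        shift <- spec$heart_rate_shift[cond]
        if (is.na(shift) || is.null(shift)) shift <- 0
        add(trial, cond, animal, "none", "heart_rate_pre", round(pre, 1))
        add(trial, cond, animal, "none", "heart_rate_post",
            round(pre + shift + stats::rnorm(1, 0, 1), 1))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assay_table", "data.frame")
  out
}
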