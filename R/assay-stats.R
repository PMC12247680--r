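.assay_get <- function(table, measure, region = NULL) {
  sel <- table$measure == measure
  if (!is.null(region)) sel <- sel & table$region == region
  table[sel, , drop = FALSE]
}

#' Trial-normalized midline UL counts and t-test
#'
#' Normalizes each animal's midline UL count by the mean count of the
#' trial's control arm, averages the normalized values per trial and
#' condition, and compares treated trial means against control trial
#' means with a two-sample t-test (plain, equal-variance, two-sided).
#' Normalizing by the control-arm mean (rather than a single designated
#' control animal) makes the statistic invariant to rescaling all counts
#' of a trial by a common factor.
#'
#' @param table An assay table (see [make_assay_tables()] for the
#'   schema).
#' @param control_condition Label of the control arm present in every
#'   trial.
#' @param treated_condition Condition to compare; defaults to the single
#'   non-control condition carrying `midline_ul_count` rows.
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @return A list with `normalized` (per-animal normalized counts),
#'   `trial_means` (per trial x condition), `estimate` (mean treated
#'   trial mean), and `p_value`.
#' @export
normalized_ul_counts <- function(table, control_condition = "DMSO",
                                 treated_condition = NULL,
                                 var_equal = TRUE) {
  ul <- .assay_get(table, "midline_ul_count")
  if (!nrow(ul)) stop("table contains no 'midline_ul_count' rows",
                      call. = FALSE)
  trials <- unique(ul$trial)
  for (tr in trials)
    if (!any(ul$trial == tr & ul$condition == control_condition))
      stop("trial '", tr, "' lacks the control condition '",
           control_condition, "'", call. = FALSE)
  conds <- setdiff(unique(ul$condition), control_condition)
  if (is.null(treated_condition)) {
    if (length(conds) != 1L)
      stop("specify 'treated_condition' (found: ",
           paste(conds, collapse = ", "), ")", call. = FALSE)
    treated_condition <- conds
  }
  ctrl_mean <- tapply(ul$value[ul$condition == control_condition],
                      ul$trial[ul$condition == control_condition], mean)
  ul$normalized <- ul$value / as.numeric(ctrl_mean[ul$trial])
  tm <- stats::aggregate(normalized ~ trial + condition, ul, mean)
  x <- tm$normalized[tm$condition == treated_condition]
  y <- tm$normalized[tm$condition == control_condition]
  p <- if (length(x) >= 2 && length(y) >= 2 &&
           (stats::sd(x) > 0 || stats::sd(y) > 0))
    stats::t.test(x, y, var.equal = var_equal)$p.value else NA_real_
  list(normalized = ul, trial_means = tm, estimate = mean(x),
       p_value = p)
}

#' Per-region EdU percentages and t-tests
#'
#' Two groupings of EdU positivity are supported. `per_heart_fraction`:
#' the percentage of EdU+ nuclei per heart
#' (`100 * edu_pos / nuclei_total`), compared between conditions per
#' region with a two-sample t-test over hearts; hearts with zero counted
#' nuclei are excluded with a warning. `per_trial_any`: the percentage
#' of animals per trial with at least one EdU+ cell in the region,
#' compared across trial percentages.
#'
#' @param table An assay table.
#' @param grouping `"per_heart_fraction"` or `"per_trial_any"`.
#' @param control_condition,treated_condition Condition labels; the
#'   treated default is the single non-control condition.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A data frame with one row per region: mean percentages per
#'   condition and the t-test p-value.
#' @export
percent_edu <- function(table,
                        grouping = c("per_heart_fraction",
                                     "per_trial_any"),
                        control_condition = "DMSO",
                        treated_condition = NULL, var_equal = TRUE) {
  grouping <- match.arg(grouping)
  pos <- .assay_get(table, "edu_pos")
  tot <- .assay_get(table, "nuclei_total")
  if (!nrow(pos)) stop("table contains no 'edu_pos' rows", call. = FALSE)
  conds <- setdiff(unique(pos$condition), control_condition)
  if (is.null(treated_condition)) {
    if (length(conds) != 1L)
      stop("specify 'treated_condition' (found: ",
           paste(conds, collapse = ", "), ")", call. = FALSE)
    treated_condition <- conds
  }
  regions <- sort(unique(pos$region))
  res <- lapply(regions, function(rg) {
    p <- pos[pos$region == rg, ]
    percents <- function(cond) {
      pp <- p[p$condition == cond, ]
      if (grouping == "per_heart_fraction") {
        tt <- tot[tot$region == rg & tot$condition == cond, ]
        denom <- tt$value[match(pp$animal, tt$animal)]
        bad <- !is.na(denom) & denom == 0
        if (any(bad))
          warning(sum(bad), " heart(s) with zero counted nuclei ",
                  "excluded in region '", rg, "'")
        keep <- !is.na(denom) & denom > 0
        100 * pp$value[keep] / denom[keep]
      } else {
        vapply(split(pp, pp$trial),
               function(d) 100 * mean(d$value >= 1), numeric(1))
      }
    }
    x <- percents(treated_condition)
    y <- percents(control_condition)
    pval <- if (length(x) >= 2 && length(y) >= 2 &&
                (stats::sd(x) > 0 || stats::sd(y) > 0))
      stats::t.test(x, y, var.equal = var_equal)$p.value else NA_real_
    data.frame(region = rg, grouping = grouping,
               mean_control = mean(y), mean_treated = mean(x),
               p_value = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled crispant morphology percentages and Fisher's exact test
#'
#' Pools abnormal-heart counts over trials per group and tests the
#' resulting 2x2 table (abnormal vs normal by group) with a two-sided
#' Fisher's exact test.
#'
#' @param counts Data frame with columns `group`, `abnormal`, `total`
#'   (one row per trial or one pooled row per group); exactly two
#'   groups.
#' @return A list with `pooled` (per-group abnormal, total and
#'   `percent_abnormal`), `table` (the pooled 2x2 matrix) and `p_value`.
#' @examples
#' crispant_morphology_test(data.frame(
#'   group = c("control", "crispant"), abnormal = c(2, 24),
#'   total = c(64, 64)))
#' @export
crispant_morphology_test <- function(counts) {
  stopifnot(all(c("group", "abnormal", "total") %in% names(counts)))
  if (any(counts$abnormal > counts$total))
    stop("'abnormal' cannot exceed 'total'", call. = FALSE)
  if (any(counts$abnormal < 0))
    stop("counts must be nonnegative", call. = FALSE)
  pooled <- stats::aggregate(cbind(abnormal, total) ~ group, counts, sum)
  if (nrow(pooled) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  pooled$percent_abnormal <- 100 * pooled$abnormal / pooled$total
  tab <- rbind(pooled$abnormal, pooled$total - pooled$abnormal)
  dimnames(tab) <- list(c("abnormal", "normal"), pooled$group)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(pooled = pooled, table = tab, p_value = p)
}

#' Paired heart-rate test
#'
#' Computes per-animal post-minus-pre heart-rate differences and a
#' two-sided paired t-test.
#'
#' @param table An assay table with `heart_rate_pre` and
#'   `heart_rate_post` rows paired by animal, or a data frame with
#'   columns `animal`, `pre`, `post`.
#' @return A list with `differences` (per animal), `mean_difference`,
#'   `statistic`, `p_value`, and `zero_variance` (`TRUE` when all
#'   differences are identical, in which case the t statistic is
#'   undefined and `p_value` is `NA` for nonzero shifts or 1 for an
#'   all-zero shift).
#' @export
paired_rate_test <- function(table) {
  if (all(c("pre", "post", "animal") %in% names(table))) {
    pre <- table$pre; post <- table$post; animals <- table$animal
  } else {
    a <- .assay_get(table, "heart_rate_pre")
    b <- .assay_get(table, "heart_rate_post")
    animals <- a$animal
    if (!setequal(a$animal, b$animal))
      stop("unpaired animal(s): ",
           paste(utils::head(c(setdiff(a$animal, b$animal),
                               setdiff(b$animal, a$animal)), 3),
                 collapse = ", "), call. = FALSE)
    pre <- a$value
    post <- b$value[match(a$animal, b$animal)]
  }
  d <- post - pre
  zero_var <- isTRUE(stats::sd(d) < 1e-12)
  if (zero_var) {
    return(list(differences = stats::setNames(d, animals),
                mean_difference = mean(d), statistic = NA_real_,
                p_value = if (all(abs(d) < 1e-12)) 1 else NA_real_,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(differences = stats::setNames(d, animals),
       mean_difference = mean(d),
       statistic = unname(tt$statistic), p_value = tt$p.value,
       zero_variance = FALSE)
}
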