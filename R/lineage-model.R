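## Cell-table engine -------------------------------------------------------
##
## A heart (or a pooled cohort of hearts) is stored as a list of parallel
## vectors, one entry per cell. Types are integer-coded for speed:
##   1 = distal_UL, 2 = midline_UL, 3 = precursor, 4 = myocyte
## cluster_end: 0 = none, 1 = dorsal, 2 = ventral.
## Positions index the UL axis: dorsal cluster <= 0, midline 1..M, ventral
## above. next_division is an absolute day (NA when the cell has no drawn
## schedule and divides by per-step Bernoulli draws).

CELL_TYPES <- c("distal_UL", "midline_UL", "precursor", "myocyte")
CLUSTER_ENDS <- c("none", "dorsal", "ventral")
# internal step used by the simulators and by division-time draws: 30 min
DT_INTERNAL <- 1 / 48

.empty_cells <- function() {
  list(heart = integer(), id = integer(), type = integer(),
       cluster_end = integer(), position = numeric(),
       birth_day = numeric(), labeled = logical(),
       founder = integer(), next_division = numeric())
}

.cells_n <- function(cl) length(cl$id)

.cells_bind <- function(a, b) {
  out <- lapply(names(a), function(nm) c(a[[nm]], b[[nm]]))
  names(out) <- names(a)
  out
}

.cells_subset <- function(cl, idx) lapply(cl, `[`, idx)

.new_heart_state <- function(day, cells, next_id, n_divisions = 0L,
                             n_hearts = 1L) {
  structure(list(day = day, cells = cells, next_id = next_id,
                 n_divisions = n_divisions, n_hearts = n_hearts),
            class = "heart_state")
}

#' @export
print.heart_state <- function(x, ...) {
  cnt <- compartment_counts(x)
  cat(sprintf("<heart_state> day %.2f, %d heart(s), %d cells (%s)\n",
              x$day, x$n_hearts, .cells_n(x$cells),
              paste(names(cnt), cnt, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tabulate a simulated heart as a data frame
#'
#' One row per cell, with decoded cell types and cluster ends.
#'
#' @param x A `heart_state`.
#' @param ... Unused.
#' @return A data frame with columns `heart`, `id`, `type`,
#'   `cluster_end`, `position`, `birth_day`, `labeled`, `founder`,
#'   `next_division`.
#' @export
as.data.frame.heart_state <- function(x, ...) {
  cl <- x$cells
  data.frame(heart = cl$heart, id = cl$id,
             type = CELL_TYPES[cl$type],
             cluster_end = CLUSTER_ENDS[cl$cluster_end + 1L],
             position = cl$position, birth_day = cl$birth_day,
             labeled = cl$labeled, founder = cl$founder,
             next_division = cl$next_division,
             stringsAsFactors = FALSE)
}

#' Count cells per compartment
#'
#' @param state A `heart_state`.
#' @param per_heart If `TRUE`, return a matrix with one row per heart in a
#'   pooled state; otherwise pooled totals.
#' @return Named integer vector (or matrix) of counts for `distal_UL`,
#'   `midline_UL`, `precursor` and `myocyte` cells.
#' @export
compartment_counts <- function(state, per_heart = FALSE) {
  stopifnot(inherits(state, "heart_state"))
  cl <- state$cells
  if (!per_heart) {
    out <- tabulate(cl$type, nbins = 4L)
    names(out) <- CELL_TYPES
    return(out)
  }
  hearts <- sort(unique(cl$heart))
  m <- matrix(0L, length(hearts), 4L,
              dimnames = list(hearts, CELL_TYPES))
  tab <- table(factor(cl$heart, levels = hearts),
               factor(cl$type, levels = 1:4))
  m[] <- as.integer(tab)
  m
}

## draw a time-to-next-division consistent with per-substep Bernoulli
## dynamics at the internal 30-min resolution (geometric waiting time)
.draw_division_time <- function(day, q, n) {
  if (n == 0L) return(numeric())
  p <- min(1, q * DT_INTERNAL)
  if (p <= 0) return(rep(Inf, n))
  day + (stats::rgeom(n, p) + 1) * DT_INTERNAL
}

#' Initialize a day-3 juvenile heart
#'
#' Draws the starting composition of a juvenile heart: two distal UL
#' clusters (dorsal and ventral) whose sizes are drawn from
#' `init_distal_per_cluster_range` (with a small probability of a rare
#' isolated singleton), a midline row sized so that the total UL falls in
#' `init_ul_total_range`, and a myocyte count drawn from
#' `init_myocyte_range`. No precursors and no labels are present at
#' initialization. If a drawn UL total cannot accommodate the distal
#' cells plus at least one midline cell, the total is redrawn (up to 100
#' attempts, after which an error is raised naming the conflicting
#' ranges).
#'
#' @param params A [lineage_params()] object.
#' @param n_hearts Number of independent hearts to initialize into a
#'   single pooled state (used by the cohort simulators); default 1.
#' @return A `heart_state` at day 3.
#' @examples
#' set.seed(1)
#' h <- init_heart(lineage_params())
#' compartment_counts(h)
#' @export
init_heart <- function(params, n_hearts = 1L) {
  validate_lineage_params(params)
  n_hearts <- as.integer(n_hearts)
  stopifnot(n_hearts >= 0L)
  if (n_hearts == 0L)
    return(.new_heart_state(3, .empty_cells(), 1L, n_hearts = 0L))

  rng_int <- function(r, n) {
    if (r[1] == r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
  }
  dcl <- params$init_distal_per_cluster_range
  dorsal <- rng_int(dcl, n_hearts)
  ventral <- rng_int(dcl, n_hearts)
  # rare isolated distal singleton, observed but not modeled mechanistically
  if (params$distal_singleton_prob > 0) {
    dorsal[stats::runif(n_hearts) < params$distal_singleton_prob] <- 1L
    ventral[stats::runif(n_hearts) < params$distal_singleton_prob] <- 1L
  }
  ul_total <- rng_int(params$init_ul_total_range, n_hearts)
  bad <- which(ul_total - (dorsal + ventral) < 1L)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 100L)
      stop("init_distal_per_cluster_range and init_ul_total_range are ",
           "inconsistent: drawn distal cells leave no room for midline ",
           "cells", call. = FALSE)
    ul_total[bad] <- rng_int(params$init_ul_total_range, length(bad))
    bad <- bad[ul_total[bad] - (dorsal[bad] + ventral[bad]) < 1L]
  }
  midline <- ul_total - dorsal - ventral
  myo <- rng_int(params$init_myocyte_range, n_hearts)

  per_heart <- dorsal + ventral + midline + myo
  heart <- rep(seq_len(n_hearts), per_heart)
  n_tot <- sum(per_heart)
  type <- integer(n_tot)
  cluster <- integer(n_tot)
  position <- rep(NA_real_, n_tot)
  off <- 0L
  for (i in seq_len(n_hearts)) {
    d <- dorsal[i]; v <- ventral[i]; m <- midline[i]; y <- myo[i]
    idx <- off + seq_len(d + v + m + y)
    type[idx] <- rep(c(1L, 2L, 1L, 4L), c(d, m, v, y))
    cluster[idx] <- rep(c(1L, 0L, 2L, 0L), c(d, m, v, y))
    position[idx] <- c(seq_len(d) - d, seq_len(m), m + seq_len(v),
                       rep(NA_real_, y))
    off <- off + d + v + m + y
  }
  cl <- list(heart = heart, id = seq_len(n_tot), type = type,
             cluster_end = cluster, position = position,
             birth_day = rep(3, n_tot), labeled = rep(FALSE, n_tot),
             founder = rep(NA_integer_, n_tot),
             next_division = rep(NA_real_, n_tot))
  .new_heart_state(3, cl, n_tot + 1L, n_hearts = n_hearts)
}

## Core synchronous division round. Every unscheduled distal/midline cell
## divides with probability q*dt; scheduled cells (and precursors, whose
## single division is always scheduled at birth + lag) divide when their
## schedule falls inside the step. Each division adds exactly one cell.
.step_cells <- function(state, params, dt, schedule_daughters = FALSE) {
  day2 <- state$day + dt
  cl <- state$cells
  n <- .cells_n(cl)
  if (n == 0L) { state$day <- day2; return(state) }

  type <- cl$type
  sched <- cl$next_division
  due <- !is.na(sched) & sched <= day2 + 1e-9
  qvec <- c(params$q_distal, params$q_midline, 0, 0)[type]
  p <- pmin(qvec * dt, 1)
  rand_div <- is.na(sched) & p > 0 & stats::runif(n) < p
  div_prog <- which((due | rand_div) & (type == 1L | type == 2L))
  div_prec <- which(due & type == 3L)
  n_events <- length(div_prog) + length(div_prec)
  if (n_events == 0L) { state$day <- day2; return(state) }

  ## per-heart midline position extremes, for inserting distal daughters
  mid <- type == 2L
  daughters <- .empty_cells()
  next_id <- state$next_id

  reschedule <- function(idx_type, n_new, day) {
    # fresh schedules for products of a division during a chase run
    if (!schedule_daughters) return(rep(NA_real_, n_new))
    q <- c(params$q_distal, params$q_midline)[idx_type]
    out <- numeric(n_new)
    for (tt in unique(idx_type)) {
      sel <- idx_type == tt
      out[sel] <- .draw_division_time(
        day, c(params$q_distal, params$q_midline)[tt], sum(sel))
    }
    out
  }

  if (length(div_prog)) {
    ptype <- type[div_prog]
    d_idx <- div_prog[ptype == 1L]     # distal parents
    m_idx <- div_prog[ptype == 2L]     # midline parents

    if (length(d_idx)) {
      # asymmetric: parent stays distal, daughter enters the midline row
      # adjacent to the parent's cluster
      hmin <- tapply(cl$position[mid], cl$heart[mid], min)
      hmax <- tapply(cl$position[mid], cl$heart[mid], max)
      hh <- as.character(cl$heart[d_idx])
      lo <- hmin[hh]; hi <- hmax[hh]
      lo[is.na(lo)] <- 1; hi[is.na(hi)] <- 0
      pos <- ifelse(cl$cluster_end[d_idx] == 1L, lo - 0.5, hi + 0.5)
      k <- length(d_idx)
      daughters <- .cells_bind(daughters, list(
        heart = cl$heart[d_idx], id = next_id + seq_len(k) - 1L,
        type = rep(2L, k), cluster_end = rep(0L, k),
        position = as.numeric(pos), birth_day = rep(day2, k),
        labeled = cl$labeled[d_idx], founder = cl$founder[d_idx],
        next_division = reschedule(rep(2L, k), k, day2)))
      next_id <- next_id + k
      cl$next_division[d_idx] <- if (schedule_daughters)
        .draw_division_time(day2, params$q_distal, k) else NA_real_
    }

    if (length(m_idx)) {
      sym <- stats::runif(length(m_idx)) < params$f_sym
      # symmetric: second midline daughter adjacent to the parent
      s_idx <- m_idx[sym]
      if (length(s_idx)) {
        k <- length(s_idx)
        daughters <- .cells_bind(daughters, list(
          heart = cl$heart[s_idx], id = next_id + seq_len(k) - 1L,
          type = rep(2L, k), cluster_end = rep(0L, k),
          position = cl$position[s_idx] + 0.25,
          birth_day = rep(day2, k),
          labeled = cl$labeled[s_idx], founder = cl$founder[s_idx],
          next_division = reschedule(rep(2L, k), k, day2)))
        next_id <- next_id + k
      }
      # asymmetric: retained midline daughter keeps the parent's slot;
      # the other daughter detaches as a precursor that will divide once
      # after the precursor lag
      a_idx <- m_idx[!sym]
      if (length(a_idx)) {
        k <- length(a_idx)
        daughters <- .cells_bind(daughters, list(
          heart = cl$heart[a_idx], id = next_id + seq_len(k) - 1L,
          type = rep(3L, k), cluster_end = rep(0L, k),
          position = rep(NA_real_, k), birth_day = rep(day2, k),
          labeled = cl$labeled[a_idx], founder = cl$founder[a_idx],
          next_division = rep(day2 + params$precursor_lag / 24, k)))
        next_id <- next_id + k
      }
      cl$next_division[m_idx] <- if (schedule_daughters)
        .draw_division_time(day2, params$q_midline, length(m_idx)) else
          NA_real_
    }
  }

  if (length(div_prec)) {
    # precursor -> two myocytes: parent differentiates, one cell added
    k <- length(div_prec)
    daughters <- .cells_bind(daughters, list(
      heart = cl$heart[div_prec], id = next_id + seq_len(k) - 1L,
      type = rep(4L, k), cluster_end = rep(0L, k),
      position = rep(NA_real_, k), birth_day = rep(day2, k),
      labeled = cl$labeled[div_prec], founder = cl$founder[div_prec],
      next_division = rep(NA_real_, k)))
    next_id <- next_id + k
    cl$type[div_prec] <- 4L
    cl$next_division[div_prec] <- NA_real_
  }

  state$cells <- .cells_bind(cl, daughters)
  state$next_id <- next_id
  state$n_divisions <- state$n_divisions + n_events
  state$day <- day2
  state
}

#' Advance a heart by one synchronous division round
#'
#' Performs a single stochastic round in which every distal UL cell
#' divides with probability `q_distal * dt` and every midline UL cell
#' with probability `q_midline * dt` (probabilities are clipped at 1).
#' Distal divisions are asymmetric: the parent remains distal and the
#' daughter is a midline cell inserted adjacent to the parent's cluster.
#' Midline divisions are symmetric with probability `f_sym` (two midline
#' daughters at adjacent positions) and otherwise asymmetric (one
#' retained midline daughter plus a detaching myocardial precursor).
#' Precursors divide exactly once, into two myocytes, when the round
#' crosses their scheduled division time (birth + `precursor_lag`).
#' Labels and founder identities are inherited by both daughters. Every
#' division adds exactly one cell.
#'
#' The cohort simulators call this round at a fixed internal resolution
#' of 30 minutes (`dt = 1/48` days).
#'
#' @param state A `heart_state`.
#' @param params A [lineage_params()] object.
#' @param dt Step duration in days; must be positive.
#' @return The advanced `heart_state`.
#' @examples
#' set.seed(1)
#' h <- init_heart(lineage_params())
#' h2 <- step_heart(h, lineage_params(), 1 / 48)
#' @export
step_heart <- function(state, params, dt) {
  stopifnot(inherits(state, "heart_state"))
  validate_lineage_params(params)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a positive duration in days", call. = FALSE)
  .step_cells(state, params, dt)
}

#' Simulate juvenile heart growth
#'
#' Initializes `n_hearts` day-3 hearts and advances them to `end_day`
#' with synchronous division rounds at a fixed 30-minute internal
#' resolution, recording one snapshot per whole day. Hearts are
#' statistically independent; they are pooled into single snapshots for
#' efficiency and can be inspected per heart via
#' [compartment_counts()] with `per_heart = TRUE`.
#'
#' @param params A [lineage_params()] object.
#' @param start_day First day (the initialization day); must be >= 3.
#' @param end_day Final day; must be >= `start_day`.
#' @param n_hearts Cohort size.
#' @return An object of class `heart_trajectory`: a list of daily
#'   `heart_state` snapshots from `start_day` to `end_day`.
#' @examples
#' set.seed(1)
#' tr <- simulate_growth(lineage_params(), end_day = 5, n_hearts = 10)
#' growth_summary(tr)
#' @export
simulate_growth <- function(params, start_day = 3, end_day, n_hearts = 1L) {
  validate_lineage_params(params)
  if (start_day < 3) stop("'start_day' must be >= 3", call. = FALSE)
  if (end_day < start_day)
    stop("'end_day' must be >= 'start_day'", call. = FALSE)
  state <- init_heart(params, n_hearts)
  state$day <- start_day
  days <- seq(start_day, end_day, by = 1)
  snapshots <- vector("list", length(days))
  snapshots[[1L]] <- state
  steps_per_day <- as.integer(round(1 / DT_INTERNAL))
  for (i in seq_along(days)[-1L]) {
    for (s in seq_len(steps_per_day))
      state <- .step_cells(state, params, DT_INTERNAL)
    snapshots[[i]] <- state
  }
  structure(snapshots, class = "heart_trajectory")
}

#' Per-day compartment growth of a simulated trajectory
#'
#' Computes, for each day of a trajectory, the mean per-heart midline-UL
#' and myocyte counts, their first differences (cells added per day), and
#' cumulative totals since the first snapshot.
#'
#' @param trajectory A `heart_trajectory` from [simulate_growth()], of
#'   length >= 2.
#' @return A data frame with columns `day`, `midline_UL`, `myocyte`,
#'   `distal_UL`, `midline_added`, `myocyte_added`,
#'   `midline_cumulative`, `myocyte_cumulative`. Counts are means over
#'   hearts; the first row has `NA` added counts.
#' @export
growth_summary <- function(trajectory) {
  stopifnot(inherits(trajectory, "heart_trajectory"))
  if (length(trajectory) < 2L)
    stop("trajectory must contain at least two snapshots", call. = FALSE)
  nh <- max(1L, trajectory[[1L]]$n_hearts)
  cnt <- t(vapply(trajectory, compartment_counts, numeric(4)))
  cnt <- cnt / nh
  day <- vapply(trajectory, `[[`, numeric(1), "day")
  out <- data.frame(
    day = day,
    midline_UL = cnt[, "midline_UL"],
    myocyte = cnt[, "myocyte"],
    distal_UL = cnt[, "distal_UL"],
    midline_added = c(NA, diff(cnt[, "midline_UL"])),
    myocyte_added = c(NA, diff(cnt[, "myocyte"])),
    midline_cumulative = cnt[, "midline_UL"] - cnt[1, "midline_UL"],
    myocyte_cumulative = cnt[, "myocyte"] - cnt[1, "myocyte"]
  )
  rownames(out) <- NULL
  out
}

## split a pooled state into per-heart states (shared day / params)
.split_hearts <- function(state) {
  cl <- state$cells
  hearts <- sort(unique(cl$heart))
  lapply(hearts, function(h) {
    sub <- .cells_subset(cl, cl$heart == h)
    sub$heart <- rep(1L, length(sub$id))
    .new_heart_state(state$day, sub, state$next_id, n_hearts = 1L)
  })
}
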