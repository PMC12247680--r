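test_that("pulse labels exactly the cells with overlapping S windows", {
  p <- lineage_params(s_window_scale_distal = 1, s_window_scale_midline = 1)
  des <- pulse_chase_design(pulse_minutes = 30, chase_hours = 0,
                            s_duration_hours = 6, g2m_hours = 2)
  # division at day 3 + 4 h: S phase spans [3 - 4h, 3 + 2h], overlapping
  # the pulse window [3, 3 + 30min] -> labeled with certainty at scale 1
  inside <- make_test_heart(data.frame(type = "midline_UL", position = 1,
                                       next_division = 3 + 4 / 24))
  got <- apply_pulse(inside, des, p)
  expect_true(got$cells$labeled)
  expect_identical(got$cells$founder, got$cells$id)
  # division two days out: S phase ends long after the pulse -> unlabeled
  outside <- make_test_heart(data.frame(type = "midline_UL", position = 1,
                                        next_division = 5))
  expect_false(apply_pulse(outside, des, p)$cells$labeled)
  # zero scale never labels
  p0 <- lineage_params(s_window_scale_distal = 0,
                       s_window_scale_midline = 0)
  set.seed(2)
  h <- init_heart(p0, n_hearts = 20)
  expect_identical(sum(apply_pulse(h, des, p0)$cells$labeled), 0L)
  # myocytes never label
  myo <- make_test_heart(data.frame(type = "myocyte",
                                    next_division = 3 + 4 / 24))
  expect_false(apply_pulse(myo, des, p)$cells$labeled)
})

test_that("proliferative index pools labeled fractions over hearts", {
  h1 <- make_test_heart(data.frame(type = rep("distal_UL", 4),
                                   labeled = c(TRUE, FALSE, FALSE, FALSE),
                                   founder = c(1, NA, NA, NA)))
  h2 <- make_test_heart(data.frame(type = rep("distal_UL", 6),
                                   labeled = rep(FALSE, 6)))
  expect_equal(proliferative_index(list(h1, h2), "distal_UL"), 0.1)
  all_lab <- make_test_heart(data.frame(type = rep("midline_UL", 3),
                                        labeled = TRUE,
                                        founder = 1:3))
  expect_equal(proliferative_index(all_lab, "midline_UL"), 1)
  expect_equal(proliferative_index(h2, "distal_UL"), 0)
  expect_error(proliferative_index(h2, "precursor"), "undefined")
})

test_that("index recovery: a known labeling probability is recovered", {
  # an S window far longer than any waiting time makes every progenitor
  # eligible, so the labeling probability equals the scale factor exactly
  p <- lineage_params(s_window_scale_distal = 0.3,
                      s_window_scale_midline = 0.1)
  des <- pulse_chase_design(pulse_minutes = 30, chase_hours = 0,
                            s_duration_hours = 24 * 400, g2m_hours = 0)
  set.seed(13)
  h <- apply_pulse(init_heart(p, 110), des, p)
  for (comp in c("distal_UL", "midline_UL")) {
    truth <- if (comp == "distal_UL") 0.3 else 0.1
    n <- sum(h$cells$type == match(comp, c("distal_UL", "midline_UL",
                                           "precursor", "myocyte")))
    se <- sqrt(truth * (1 - truth) / n)
    expect_lt(abs(proliferative_index(h, comp) - truth), 3 * se)
  }
})

test_that("division rate estimator applies zero-exclusion and scaling", {
  expect_equal(division_rate_estimate(c(1, 1, 0), c(3, 0, 3), 36), 2)
  expect_equal(division_rate_estimate(c(2, 2), c(2, 2), 36), 2 / 3)
  # identity: chase mean 1.5x pulse mean at 36 h gives exactly 1
  for (s in 1:1000) {
    set.seed(s)
    x <- sample(1:6, 8, replace = TRUE)
    expect_equal(division_rate_estimate(c(x, 0), c(1.5 * x, 0), 36), 1)
  }
  expect_error(division_rate_estimate(c(0, 0), c(1, 2), 36), "zero")
  expect_error(division_rate_estimate(c(1, 2), c(1, 2), 0), "positive")
})

test_that("chase inherits labels and the census partitions them", {
  p <- lineage_params()
  des <- pulse_chase_design(30, 72)
  set.seed(17)
  cohort <- make_heart_cohort(p, 60, 3)
  pulsed <- lapply(cohort, apply_pulse, design = des, params = p)
  n_lab0 <- sum(vapply(pulsed, function(h) sum(h$cells$labeled), 0L))
  res <- lapply(pulsed, chase, design = des, params = p)
  census <- do.call(rbind, lapply(res, clone_census))
  # heritability: labeled founders never lost, clones partition labels
  n_lab1 <- sum(vapply(res, function(r) sum(r$chase_state$cells$labeled),
                       0L))
  expect_gte(n_lab1, n_lab0)
  expect_identical(sum(census$n_cells), n_lab1)
  # every labeled cell's founder chain terminates at a pulse-labeled cell
  for (r in res) {
    cl <- r$chase_state$cells
    lab <- which(cl$labeled)
    expect_false(anyNA(cl$founder[lab]))
    expect_true(all(cl$founder[lab] %in% r$pulse_state$cells$id[
      r$pulse_state$cells$labeled]))
  }
})

test_that("chase-free clones are singletons and census is empty when unlabeled", {
  p <- lineage_params()
  des <- pulse_chase_design(30, 0)
  set.seed(19)
  h <- apply_pulse(init_heart(p, 40), des, p)
  res <- chase(h, des, p)
  census <- clone_census(res)
  if (nrow(census)) expect_true(all(census$n_cells == 1L))
  unlab <- init_heart(p, 5)
  expect_identical(nrow(clone_census(chase(unlab, des, p))), 0L)
})

test_that("72-hour clones show the observed size range and compositions", {
  p <- lineage_params()
  des <- pulse_chase_design(30, 72)
  set.seed(23)
  cohort <- make_heart_cohort(p, 250, 3)
  pulsed <- lapply(cohort, apply_pulse, design = des, params = p)
  res <- lapply(pulsed, chase, design = des, params = p)
  census <- do.call(rbind, lapply(res, clone_census))
  expect_gt(nrow(census), 20)
  # clusters of 1-4 labeled cells dominate
  expect_gt(mean(census$n_cells <= 4), 0.5)
  expect_true(all(c(2, 3) %in% census$n_cells))
  # paired distal+midline clones at the distal ends
  expect_true("distal_UL+midline_UL" %in% census$composition)
  # midline pairs and precursor-family clones (two midline cells with a
  # precursor, or with the precursor's two myocyte daughters)
  has_two_mid <- grepl("midline_UL\\+midline_UL", census$composition)
  expect_true(any(has_two_mid))
  expect_true(any(grepl("precursor|myocyte", census$composition)))
})

test_that("multi-labeled hearts after a 30-minute pulse are rare", {
  p <- lineage_params()
  des <- pulse_chase_design(30, 0)
  set.seed(29)
  h <- apply_pulse(init_heart(p, 1000), des, p)
  cl <- h$cells
  lab_ul <- tapply(cl$labeled & cl$type %in% 1:2, cl$heart, sum)
  expect_lt(mean(lab_ul >= 2), 0.10)
  # and most hearts carry no label at all, as observed
  expect_gt(mean(lab_ul == 0), 0.5)
})

test_that("deterministic schedules reproduce a hand-enumerated clone tree", {
  # one labeled midline cell scheduled to divide 6 h after the pulse;
  # f_sym = 0 forces midline + precursor; the precursor divides exactly
  # once 12 h later into two myocytes; hazards are zero so nothing else
  # divides
  p <- lineage_params(q_distal = 0, q_midline = 0, f_sym = 0,
                      precursor_lag = 12)
  des <- pulse_chase_design(30, 36)
  h <- make_test_heart(data.frame(type = "midline_UL", position = 1,
                                  labeled = TRUE, founder = 1,
                                  next_division = 3 + 6 / 24))
  res <- chase(h, des, p)
  census <- clone_census(res)
  expect_identical(nrow(census), 1L)
  expect_identical(census$n_cells, 3L)
  expect_identical(census$composition, "midline_UL+myocyte+myocyte")
  expect_identical(res$chase_state$n_divisions, 2L)
})
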