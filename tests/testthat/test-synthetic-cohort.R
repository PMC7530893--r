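# synthetic cohort generator

test_that("ground truth is reproducible and validates its inputs", {
  gt1 <- make_ground_truth(n_regions = 30, k_true = 2, community_sizes = c(5, 6),
                           occupancy_by_group = list(low = c(0.4, 0.6)),
                           seed = 9)
  gt2 <- make_ground_truth(n_regions = 30, k_true = 2, community_sizes = c(5, 6),
                           occupancy_by_group = list(low = c(0.4, 0.6)),
                           seed = 9)
  expect_identical(gt1$communities, gt2$communities)
  expect_false(identical(gt1$communities[[1]], gt1$communities[[2]]))

  expect_error(make_ground_truth(n_regions = 30, k_true = 2,
                                 occupancy_by_group = list(low = c(0.9, 0.3)),
                                 seed = 1),
               "sum to 1")
  expect_error(make_ground_truth(n_regions = 30, k_true = 2,
                                 community_sizes = c(20, 5),
                                 occupancy_by_group = list(low = c(0.5, 0.5)),
                                 seed = 1),
               "half the regions")
  expect_error(make_ground_truth(carrier_freq = 0.2, seed = 1), "band")
})

test_that("default ground truth matches the emulated study layout", {
  gt <- make_ground_truth(seed = 1)
  expect_equal(gt$n_regions, 223)
  expect_equal(gt$k_true, 9)
  expect_true(all(lengths(gt$communities) < 223 / 2))
  expect_equal(length(gt$communities), 9)
  expect_equal(sum(gt$occupancy_profile$low), 1)
  expect_equal(sum(gt$occupancy_profile$high), 1)
  expect_equal(gt$gender_composition, list(low = c(21, 29), high = c(16, 3)))
})

test_that("hidden occupancy matches the planted profile (stationarity oracle)", {
  # oracle: the chain is built so its stationary law IS the profile; a long
  # realization must agree within 3 standard errors (effective n reduced by
  # the geometric dwell autocorrelation)
  gt <- make_ground_truth(n_regions = 10, k_true = 2, community_sizes = c(2, 2),
                          occupancy_by_group = list(low = c(0.7, 0.3)),
                          dwell_mean = 3, seed = 5)
  sub <- simulate_subject(gt, "low", "F", n_volumes = 5000, seed = 11)
  occ <- mean(sub$hidden_labels == 1)
  # dwell in state 1 is geometric mean d/(1-pi1); approximate the SE of the
  # occupancy of a two-state renewal process via the effective sample size
  d1 <- 3 / (1 - 0.7)
  se <- sqrt(0.7 * 0.3 / (5000 / (2 * d1)))
  expect_lt(abs(occ - 0.7), 3 * se)
  # per-state dwell means are geometric with mean d/(1 - pi_s)
  r <- rle(sub$hidden_labels)
  expect_equal(mean(r$lengths[r$values == 1]), 3 / (1 - 0.7),
               tolerance = 0.15)
  expect_equal(mean(r$lengths[r$values == 2]), 3 / (1 - 0.3),
               tolerance = 0.15)
})

test_that("zero jitter and noise give perfect within-community phase locking", {
  sub <- simulate_subject(gt_clean, "low", "M", n_volumes = 30, seed = 2)
  # at every frame, members of the active community share one phase:
  # all pairwise PL entries among them are exactly cos(0) = 1
  for (t in seq_len(30)) {
    memb <- gt_clean$communities[[sub$hidden_labels[t]]]
    pl <- phase_locking_matrix(sub$phase[, t])
    expect_equal(max(abs(pl[memb, memb] - 1)), 0, tolerance = 1e-12)
  }
})

test_that("subjects and cohorts are bit-reproducible under a fixed seed", {
  s1 <- simulate_subject(gt_clean, "high", "F", n_volumes = 40, seed = 13)
  s2 <- simulate_subject(gt_clean, "high", "F", n_volumes = 40, seed = 13)
  expect_identical(s1$series, s2$series)
  co1 <- simulate_cohort(gt_clean, n_low = 2, n_high = 2, n_volumes = 20,
                         base_seed = 4)
  co2 <- simulate_cohort(gt_clean, n_low = 2, n_high = 2, n_volumes = 20,
                         base_seed = 4)
  expect_identical(co1$series, co2$series)
})

test_that("cohorts have the requested layout and gender composition", {
  co <- simulate_cohort(gt_clean, n_low = 50, n_high = 19, n_volumes = 10,
                        base_seed = 1)
  expect_equal(nrow(co$subjects), 69)
  expect_true(all(vapply(co$series, ncol, integer(1)) == 10))
  tab <- table(co$subjects$group, co$subjects$gender)
  expect_equal(unname(tab["high", "F"]), 16)
  expect_equal(unname(tab["high", "M"]), 3)
  expect_equal(unname(tab["low", "F"]), 21)
  expect_equal(unname(tab["low", "M"]), 29)
})

test_that("degenerate inputs are rejected", {
  expect_error(simulate_subject(gt_clean, "nosuch", "F", seed = 1),
               "occupancy profile")
  expect_error(simulate_subject(gt_clean, "low", "F", n_volumes = 3, seed = 1),
               "at least 4")
  # single-group cohort: downstream group statistics must refuse
  co <- simulate_cohort(gt_clean, n_low = 4, n_high = 0, n_volumes = 20,
                        base_seed = 2)
  prof <- tibble::tibble(subject_id = co$subjects$subject_id,
                         state = 1, occupancy = runif(4))
  expect_error(compare_states(prof, co$subjects, "occupancy", strata = NULL,
                              n_perm = 10, seed = 1),
               "two groups")
})

test_that("cohorts round-trip through the on-disk text layout", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(gt_clean, n_low = 2, n_high = 1, n_volumes = 12,
                        base_seed = 5)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$series, co$series, tolerance = 1e-12)
  expect_equal(back$subjects$group, co$subjects$group)
  expect_equal(back$tr, co$tr)
})
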