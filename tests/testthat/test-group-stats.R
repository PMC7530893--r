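# stratified permutation tests, FDR, effect sizes, demographics, motion QC

test_that("permutation p matches exhaustive within-strata enumeration (oracle)", {
  # 4 subjects in one stratum, 2 per group: choose(4, 2) = 6 arrangements;
  # with n_perm large the Monte-Carlo p must converge to the exhaustive one
  values <- c(1.0, 2.0, 10.0, 11.0)
  groups <- c("a", "a", "b", "b")
  t_of <- function(ix) {
    x1 <- values[ix]
    x2 <- values[-ix]
    sp2 <- (var(x1) + var(x2)) / 2
    abs((mean(x1) - mean(x2)) / sqrt(sp2))
  }
  t_obs <- t_of(1:2)
  t_all <- apply(combn(4, 2), 2, t_of)
  p_exact <- mean(t_all >= t_obs - 1e-12)
  res <- perm_ttest_restricted(values, groups, NULL, n_perm = 4000, seed = 3)
  expect_equal(res$p_perm, p_exact, tolerance = 0.05)
  expect_gt(res$p_perm, 0)
})

test_that("stratified permutations shuffle only within strata", {
  # the group effect is perfectly confounded with the stratum: restricted
  # permutations can never separate them, so p stays 1
  values <- c(10, 11, 12, 1, 2, 3)
  groups <- c("a", "a", "a", "b", "b", "b")
  strata <- groups
  expect_warning(
    res <- perm_ttest_restricted(values, groups, strata, n_perm = 200,
                                 seed = 1),
    NA
  )
  expect_equal(res$p_perm, 1)
})

test_that("degenerate and constant inputs behave as defined", {
  res <- perm_ttest_restricted(rep(5, 8), rep(c("a", "b"), 4), NULL,
                               n_perm = 100, seed = 2)
  expect_equal(res$t_observed, 0)
  expect_equal(res$p_perm, 1)
  expect_warning(
    perm_ttest_restricted(c(1, 2, 3), c("a", "b", "b"),
                          c("s1", "s2", "s2"), n_perm = 50, seed = 1),
    "single subject"
  )
})

test_that("permutation p is invariant to group relabeling (two-sidedness)", {
  set.seed(54)
  values <- rnorm(16)
  groups <- rep(c("a", "b"), 8)
  strata <- rep(c("F", "M"), each = 8)
  p1 <- perm_ttest_restricted(values, groups, strata, n_perm = 500, seed = 7)
  flipped <- ifelse(groups == "a", "b", "a")
  p2 <- perm_ttest_restricted(values, flipped, strata, n_perm = 500, seed = 7)
  expect_equal(p1$p_perm, p2$p_perm)
  expect_equal(p1$t_observed, -p2$t_observed)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.8)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("Hedges' g reproduces printed effect sizes and its algebra", {
  expect_equal(round(hedges_g(19, 16.1, 8.8, 50, 9.8, 8.0), 2), 0.77)
  expect_equal(round(abs(hedges_g(19, 6.2, 3.4, 50, 10.6, 6.6)), 2), 0.74)
  expect_equal(round(hedges_g(19, 6.8, 2.9, 50, 5.0, 2.6), 2), 0.67)
  expect_equal(round(abs(hedges_g(19, 4.1, 2.0, 50, 5.5, 2.3)), 2), 0.63)
  expect_equal(hedges_g(10, 5, 2, 10, 5, 2), 0)
  expect_equal(hedges_g(19, 5.5, 2, 50, 4.1, 3),
               -hedges_g(50, 4.1, 3, 19, 5.5, 2))
  # small-sample correction shrinks toward zero
  g <- hedges_g(8, 3, 1, 9, 2, 1)
  gc <- hedges_g(8, 3, 1, 9, 2, 1, small_sample_correction = TRUE)
  expect_lt(abs(gc), abs(g))
  expect_equal(gc / g, 1 - 3 / (4 * 15 - 1))
  expect_error(hedges_g(5, 1, 0, 5, 1, 0), "pooled SD")
})

test_that("chi-square matches the definitional formula (direct oracle)", {
  tab <- matrix(c(16, 21, 3, 29), 2)   # women/men by group
  res <- chi2_2x2(tab)
  expect_equal(round(res$statistic, 1), 9.9)
  expect_equal(res$df, 1)
  expect_equal(chi2_2x2(matrix(10, 2, 2))$statistic, 0)
  set.seed(55)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(chi2_2x2(t2)$statistic, sum((t2 - e)^2 / e),
                 tolerance = 1e-10)
  }
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("framewise displacement matches the finite-difference oracle", {
  zero <- matrix(0, 10, 6)
  expect_equal(mean_fd(zero)$mean_fd, 0)
  step <- zero
  step[6:10, 1] <- 1   # single 1 mm x-translation step
  fd <- mean_fd(step)
  expect_equal(sum(fd$fd_trace), 1)
  expect_equal(sort(unique(fd$fd_trace)), c(0, 1))
  set.seed(56)
  mp <- matrix(rnorm(12 * 6, sd = 0.1), 12, 6)
  got <- mean_fd(mp, rotation_radius_mm = 50)
  man <- sapply(2:12, function(t) {
    sum(abs(mp[t, 1:3] - mp[t - 1, 1:3])) +
      50 * sum(abs(mp[t, 4:6] - mp[t - 1, 4:6]))
  })
  expect_equal(got$fd_trace, man)
  expect_equal(got$mean_fd, mean(man))
  expect_error(mean_fd(matrix(0, 1, 6)), "2 frames")
  expect_error(mean_fd(matrix(0, 5, 5)), "6 columns")
})

test_that("compare_states tests each state and adjusts within the model", {
  set.seed(57)
  n <- 24
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("low", "high"), each = n / 2),
    gender = rep(c("F", "M"), n / 2)
  )
  prof <- tidyr::expand_grid(subject_id = subjects$subject_id, state = 1:3) |>
    dplyr::mutate(occupancy = rnorm(dplyr::n()),
                  lifetime = rnorm(dplyr::n()))
  # plant a large effect on state 2 occupancy
  hi <- prof$state == 2 &
    prof$subject_id %in% subjects$subject_id[subjects$group == "high"]
  prof$occupancy[hi] <- prof$occupancy[hi] + 4
  res <- compare_states(prof, subjects, "occupancy", strata = "gender",
                        n_perm = 400, seed = 5)
  expect_equal(nrow(res), 3)
  expect_lt(res$p_fdr[res$state == 2], 0.05)
  expect_true(all(res$p_fdr >= res$p_perm))
  expect_gt(res$g[res$state == 2], 1)    # high minus low, large positive
  # lifetime NA handling: never-visited subjects drop from that state's test
  prof$lifetime[1] <- NA
  res_lt <- compare_states(prof, subjects, "lifetime", strata = "gender",
                           n_perm = 100, seed = 6)
  expect_equal(res_lt$n_1[res_lt$state == 1] +
                 res_lt$n_2[res_lt$state == 1], n - 1)
})
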