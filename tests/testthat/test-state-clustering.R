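# k-means state detection, cross-k matching, community extraction

test_that("exactly repeated vectors are recovered with zero inertia", {
  v1 <- c(1, 0, 0, 0) / 1
  v2 <- c(0, 1, 0, 0)
  x <- rbind(v1, v1, v1, v2, v2, v2)
  pt <- kmeans_partition(x, k = 2, n_init = 5, seed = 1)
  expect_equal(pt$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(pt$sizes), c(3, 3))
  # each centroid equals one input direction (up to sign convention)
  sims <- abs(pt$centroids %*% cbind(v1, v2))
  expect_equal(unname(sort(apply(sims, 1, max))), c(1, 1), tolerance = 1e-12)
})

test_that("k equal to the pool size gives zero inertia", {
  set.seed(41)
  x <- matrix(rnorm(4 * 6), 4, 6)
  x <- x / sqrt(rowSums(x^2))
  pt <- kmeans_partition(x, k = 4, n_init = 20, seed = 2)
  expect_equal(pt$inertia, 0, tolerance = 1e-10)
})

test_that("partitions are deterministic given the seed and validate inputs", {
  p1 <- kmeans_partition(pool_clean, k = 3, n_init = 3, seed = 5)
  p2 <- kmeans_partition(pool_clean, k = 3, n_init = 3, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$centroids, p2$centroids)
  expect_error(kmeans_partition(pool_clean, k = 1), "at least 2")
  expect_error(kmeans_partition(matrix(rnorm(8), 2, 4), k = 3), "fewer pool rows")
})

test_that("labels are exhaustive and exclusive; centroids follow the convention", {
  pt <- kmeans_partition(pool_clean, k = 4, n_init = 5, seed = 6)
  expect_equal(sum(pt$sizes), nrow(pool_clean$vectors))
  expect_true(all(pt$labels %in% 1:4))
  expect_true(all(pt$sizes > 0))
  for (s in 1:4) {
    v <- pt$centroids[s, ]
    expect_gte(sum(v < 0), sum(v > 0))
  }
})

test_that("planted two-state structure is recovered at zero noise", {
  pt <- kmeans_partition(pool_clean, k = 2, n_init = 10, seed = 5)
  hidden <- hidden_trimmed(cohort_clean)
  expect_gte(label_agreement(pt$labels, hidden, 2), 0.95)
  # each centroid's positive set matches a planted community
  for (s in 1:2) {
    truth <- gt_clean$communities[[s]]
    best <- max(apply(pt$centroids, 1, function(v) {
      ind <- as.numeric(v > 0)
      tr <- as.numeric(seq_along(v) %in% truth)
      sum(ind * tr) / sqrt(sum(ind) * sum(tr))
    }))
    expect_gt(best, 0.9)
  }
})

test_that("the k sweep returns one reproducible model per k", {
  sw <- sweep_k(pool_clean, k_min = 2, k_max = 4, n_init = 3, seed = 8)
  expect_length(sw, 3)
  expect_equal(names(sw), c("k2", "k3", "k4"))
  sw2 <- sweep_k(pool_clean, k_min = 2, k_max = 4, n_init = 3, seed = 8)
  expect_identical(lapply(sw, `[[`, "labels"), lapply(sw2, `[[`, "labels"))
  expect_length(sweep_k(pool_clean, k_min = 4, k_max = 4, n_init = 2, seed = 1), 1)
})

test_that("cross-k matching links duplicated centroids and ignores orthogonal ones", {
  base <- diag(4)[1:2, ]
  m1 <- list(k = 2L, centroids = base, labels = c(1L, 2L))
  m2 <- list(k = 3L, centroids = rbind(base, c(0, 0, 1, 0)),
             labels = c(1L, 2L, 3L))
  class(m1) <- class(m2) <- "pl_partition"
  cm <- match_states_across_k(list(m1, m2), min_similarity = 0.8)
  expect_equal(nrow(cm$edges), 2)
  fam <- cm$families
  # duplicated centroids share a family; the orthogonal extra state is alone
  f1 <- fam$family[fam$k == 2 & fam$state == 1]
  expect_equal(fam$family[fam$k == 3 & fam$state == 1], f1)
  extra <- fam$family[fam$k == 3 & fam$state == 3]
  expect_false(extra %in% fam$family[fam$k == 2])
})

test_that("planted families span the whole sweep on a clean cohort", {
  sw <- sweep_k(pool_clean, k_min = 2, k_max = 4, n_init = 10, seed = 9)
  cm <- match_states_across_k(sw)
  planted <- lapply(gt_clean$communities, function(tr) {
    as.numeric(seq_len(gt_clean$n_regions) %in% tr)
  })
  for (p in planted) {
    fams <- unlist(lapply(sw, function(m) {
      sims <- apply(m$centroids, 1, function(v) {
        ind <- as.numeric(v > 0)
        if (sum(ind) == 0) return(0)
        sum(ind * p) / sqrt(sum(ind) * sum(p))
      })
      s <- which.max(sims)
      cm$families$family[cm$families$k == m$k & cm$families$state == s]
    }))
    expect_length(unique(fams), 1)   # one family across all k
  }
})

test_that("community_split returns the positive minority and keeps strengths", {
  v <- c(rep(-0.2, 213), rep(0.3, 10))
  cs <- community_split(v)
  expect_equal(cs$smallest, 214:223)
  expect_length(cs$largest, 213)
  expect_equal(cs$strength, abs(v))
  all_neg <- community_split(rep(-0.1, 20))
  expect_length(all_neg$smallest, 0)  # global mode: legal, empty smallest
  expect_length(all_neg$largest, 20)
})

test_that("centroid outer products are rank-1 with the centroid as eigenvector", {
  expect_equal(centroid_outer_product(rep(1 / 2, 4)), matrix(1 / 4, 4, 4))
  v2 <- c(rep(1, 2), rep(-1, 3)) / sqrt(5)
  op <- centroid_outer_product(v2)
  expect_true(all(op[1:2, 1:2] > 0) && all(op[3:5, 3:5] > 0))
  expect_true(all(op[1:2, 3:5] < 0))
  set.seed(42)
  v <- rnorm(8)
  v <- v / sqrt(sum(v^2))
  e <- eigen(centroid_outer_product(v), symmetric = TRUE)
  expect_equal(e$values[1], 1, tolerance = 1e-10)
  expect_equal(abs(sum(e$vectors[, 1] * v)), 1, tolerance = 1e-10)
})
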