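# static FC and the network-based statistic

test_that("static FC matches the definitional correlation (oracle)", {
  set.seed(61)
  x <- matrix(rnorm(5 * 40), 5, 40)
  fc <- static_fc(x)
  expect_true(all(is.na(diag(fc))))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      num <- cov(x[i, ], x[j, ])
      expect_equal(fc[i, j], num / (sd(x[i, ]) * sd(x[j, ])))
      expect_equal(fc[i, j], fc[j, i])
    }
  }
  # duplicated region pair
  y <- rbind(x, x[1, ])
  expect_equal(static_fc(y)[1, 6], 1)
  expect_error(static_fc(rbind(x, 0)), "zero-variance")
})

test_that("edgewise GLM t equals the classical two-sample t without covariates", {
  set.seed(62)
  n <- 20
  edges <- matrix(rnorm(n * 15), n, 15)
  group <- rep(c(0, 1), each = n / 2)
  tt <- edgewise_glm_t(edges, group)
  for (e in 1:15) {
    cl <- t.test(edges[group == 1, e], edges[group == 0, e],
                 var.equal = TRUE)
    expect_equal(tt[e], unname(cl$statistic), tolerance = 1e-10)
  }
})

test_that("a covariate that explains the edge absorbs the group effect", {
  set.seed(63)
  n <- 40
  covar <- rnorm(n)
  group <- rep(c(0, 1), n / 2)          # orthogonal to covar in expectation
  edges <- cbind(5 * covar)             # edge fully explained by the covariate
  t_with <- edgewise_glm_t(edges, group, covariates = covar)
  expect_lt(abs(t_with), 1e-8)
  # consistent subject permutation leaves t unchanged
  edges2 <- matrix(rnorm(n * 3), n)
  p <- sample(n)
  expect_equal(edgewise_glm_t(edges2, group, covariates = covar),
               edgewise_glm_t(edges2[p, ], group[p], covariates = covar[p]))
  expect_error(edgewise_glm_t(edges2, rep(1, n)), "rank deficient")
})

test_that("the t map is antisymmetric in a group-label swap", {
  set.seed(64)
  edges <- matrix(rnorm(30 * 10), 30, 10)
  g <- rep(c(0, 1), 15)
  expect_equal(edgewise_glm_t(edges, g), -edgewise_glm_t(edges, 1 - g),
               tolerance = 1e-10)
})

test_that("suprathreshold components match a brute-force flood fill (oracle)", {
  set.seed(65)
  n <- 12
  for (i in 1:10) {
    t_map <- rnorm(n * (n - 1) / 2)
    comps <- suprathreshold_components(t_map, n, threshold = 0.8,
                                       tail = "positive")
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- t_map > 0.8
    oracle <- bfs_components(idx[sel, , drop = FALSE])
    expect_equal(length(comps), length(oracle))
    got_nodes <- lapply(comps, `[[`, "nodes")
    expect_setequal(lapply(got_nodes, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # edge counts sum to the suprathreshold total
    expect_equal(sum(vapply(comps, `[[`, numeric(1), "n_edges")), sum(sel))
    # internal max-component-size agrees with the igraph-based route
    expect_equal(plstates:::max_component_size(idx[sel, , drop = FALSE]),
                 if (length(comps)) comps[[1]]$n_edges else 0L)
  }
})

test_that("planted structures are found; empty maps are legal", {
  # a 5-edge path: one component with 6 nodes
  n <- 10
  t_map <- rep(0, n * (n - 1) / 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  path_edges <- cbind(1:5, 2:6)
  for (r in 1:5) {
    t_map[idx[, 1] == path_edges[r, 1] & idx[, 2] == path_edges[r, 2]] <- 5
  }
  comps <- suprathreshold_components(t_map, n, 3.5, "positive")
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 5)
  expect_length(comps[[1]]$nodes, 6)
  expect_length(suprathreshold_components(rep(0, 45), 10, 3.5, "positive"), 0)
  # negative tail picks up the mirrored effect
  expect_length(suprathreshold_components(-t_map, n, 3.5, "negative"), 1)
})

test_that("raising the threshold never grows a component", {
  set.seed(66)
  n <- 15
  t_map <- rnorm(n * (n - 1) / 2, sd = 2)
  sizes <- vapply(c(3.1, 3.5, 4), function(T) {
    comps <- suprathreshold_components(t_map, n, T, "positive")
    if (length(comps)) comps[[1]]$n_edges else 0L
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("node degrees match the adjacency row sums (oracle)", {
  star <- list(edges = cbind(1, 2:10))
  deg <- degree_per_node(star)
  expect_equal(deg$degree[deg$node == 1], 9)
  expect_true(all(deg$degree[deg$node != 1] == 1))
  single <- degree_per_node(list(edges = cbind(3, 7)))
  expect_equal(single$degree, c(1, 1))
  set.seed(67)
  e <- cbind(sample(1:8, 12, TRUE), sample(9:15, 12, TRUE))
  adj <- matrix(0, 15, 15)
  for (r in 1:12) {
    adj[e[r, 1], e[r, 2]] <- adj[e[r, 1], e[r, 2]] + 1
    adj[e[r, 2], e[r, 1]] <- adj[e[r, 2], e[r, 1]] + 1
  }
  deg2 <- degree_per_node(list(edges = e))
  expect_equal(deg2$degree, unname(rowSums(adj))[deg2$node])
})

test_that("NBS detects a planted dense subnetwork and is deterministic", {
  set.seed(68)
  n_sub <- 30
  n_reg <- 12
  group <- rep(c(0, 1), each = n_sub / 2)   # 1 = the affected group
  # FC matrices: planted strong group effect on the clique 1..5
  fc <- lapply(1:n_sub, function(i) {
    m <- matrix(rnorm(n_reg^2, sd = 0.1), n_reg)
    m <- (m + t(m)) / 2
    if (group[i] == 1) m[1:5, 1:5] <- m[1:5, 1:5] + 1
    diag(m) <- NA
    m
  })
  res <- nbs(fc, group, threshold = 3.5, tail = "positive", n_perm = 200,
             seed = 9)
  expect_gte(length(res$components), 1)
  expect_lt(res$components[[1]]$p_fwer, 0.05)
  expect_true(all(res$components[[1]]$nodes %in% 1:5))
  res2 <- nbs(fc, group, threshold = 3.5, tail = "positive", n_perm = 200,
              seed = 9)
  expect_identical(res$null_max_sizes, res2$null_max_sizes)
  expect_identical(tidy(res), tidy(res2))
  gl <- glance(res)
  expect_equal(gl$n_components, length(res$components))
})
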