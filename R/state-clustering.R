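# Detection of recurrent phase-locking states by k-means over pooled
# leading eigenvectors.
#
# The default metric is cosine distance: leading eigenvectors are unit-norm
# directions, so states are directions too and the natural assignment is by
# maximal cosine similarity (spherical k-means: Lloyd iterations with
# centroid = renormalized mean). A Euclidean route through stats::kmeans is
# available by flag.

# one spherical k-means run from a given start; rows of `x` are unit norm
spherical_kmeans_once <- function(x, k, max_iter, start_idx) {
  centroids <- x[start_idx, , drop = FALSE]
  labels <- integer(nrow(x))
  for (iter in seq_len(max_iter)) {
    sim <- x %*% t(centroids)                 # n x k cosine similarity
    new_labels <- max.col(sim, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      rows <- labels == j
      if (!any(rows)) return(NULL)            # empty cluster: caller restarts
      m <- colMeans(x[rows, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm == 0) return(NULL)
      centroids[j, ] <- m / nm
    }
  }
  sim <- x %*% t(centroids)
  best <- sim[cbind(seq_len(nrow(x)), labels)]
  list(centroids = centroids, labels = labels,
       inertia = sum(1 - best))               # total cosine distance
}

#' Partition pooled eigenvectors into k recurrent states
#'
#' Runs k-means with `n_init` restarts and keeps the solution with the
#' lowest objective (summed cosine distance to the assigned centroid for the
#' default metric; within-cluster sum of squares for Euclidean). Centroid
#' rows are put through the same sign convention as the eigenvectors, so a
#' centroid's positive elements are the state's smallest phase community.
#'
#' @param pool a `pl_pool` from [build_pool()], or a plain numeric matrix of
#'   row vectors.
#' @param k number of states (at least 2).
#' @param n_init random restarts (default 50).
#' @param max_iter Lloyd iterations per restart (default 500).
#' @param seed integer seed; the partition is deterministic given it.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return a `pl_partition`: `k`, `centroids` (k x N), `labels` (one state
#'   index in 1..k per pool row), `inertia`, `sizes`, `seed`, `metric`, and
#'   the pool `index`.
#' @export
kmeans_partition <- function(pool, k, n_init = 50, max_iter = 500,
                             seed = 1L, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  x <- if (inherits(pool, "pl_pool")) pool$vectors else as.matrix(pool)
  index <- if (inherits(pool, "pl_pool")) pool$index else NULL
  abort_if(k < 2, "`k` must be at least 2")
  abort_if(nrow(x) < k, "fewer pool rows than clusters")

  best <- NULL
  if (metric == "cosine") {
    xn <- x / sqrt(rowSums(x^2))
    with_seed(seed, {
      attempts <- 0
      runs <- 0
      while (runs < n_init && attempts < n_init * 10) {
        attempts <- attempts + 1
        start <- sample.int(nrow(xn), k)
        fit <- spherical_kmeans_once(xn, k, max_iter, start)
        if (is.null(fit)) next                 # empty cluster, redraw start
        runs <- runs + 1
        if (is.null(best) || fit$inertia < best$inertia) best <- fit
      }
    })
    abort_if(is.null(best),
             "k-means failed: empty cluster in every restart attempt")
  } else {
    fit <- with_seed(seed, {
      stats::kmeans(x, centers = k, nstart = n_init, iter.max = max_iter)
    })
    best <- list(centroids = fit$centers, labels = fit$cluster,
                 inertia = fit$tot.withinss)
  }

  centroids <- t(apply(best$centroids, 1, apply_sign_convention))
  structure(
    list(k = as.integer(k), centroids = centroids, labels = best$labels,
         inertia = best$inertia, sizes = tabulate(best$labels, k),
         seed = as.integer(seed), metric = metric, index = index),
    class = "pl_partition"
  )
}

#' @export
print.pl_partition <- function(x, ...) {
  cat(sprintf("<pl_partition> k = %d (%s), %d frames, objective %.4g\n",
              x$k, x$metric, length(x$labels), x$inertia))
  cat("  state sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Run the clustering over a range of k
#'
#' One partition model per k in `k_min:k_max` (the conventional sweep
#' k = 4..14 yields 11 models), each independently and reproducibly seeded.
#'
#' @inheritParams kmeans_partition
#' @param k_min,k_max sweep bounds (defaults 4 and 14).
#' @param seed base seed; model k uses a seed derived from it.
#' @return a `pl_sweep`: named list of `pl_partition` (names `"k4"`, ...).
#' @export
sweep_k <- function(pool, k_min = 4, k_max = 14, n_init = 50, max_iter = 500,
                    seed = 1L, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  abort_if(k_min > k_max, "`k_min` must not exceed `k_max`")
  ks <- seq.int(k_min, k_max)
  seeds <- derive_seeds(seed, length(ks))
  models <- purrr::map2(ks, seeds, function(k, s) {
    kmeans_partition(pool, k, n_init = n_init, max_iter = max_iter,
                     seed = s, metric = metric)
  })
  structure(setNames(models, paste0("k", ks)), class = "pl_sweep")
}

#' @export
print.pl_sweep <- function(x, ...) {
  cat(sprintf("<pl_sweep> %d partition models: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Match variant forms of the same state across partition models
#'
#' Centroids of adjacent k are linked when their Pearson correlation reaches
#' `min_similarity`; families are the connected groups of linked states
#' (transitive closure), identifying variant forms of one underlying
#' phase-locking configuration across the sweep.
#'
#' @param models a `pl_sweep` or list of `pl_partition` objects.
#' @param min_similarity Pearson threshold for linking (default 0.8).
#' @return a `pl_crossk`: list with `edges` (tibble: k_a, state_a, k_b,
#'   state_b, similarity) and `families` (tibble: k, state, family).
#' @export
match_states_across_k <- function(models, min_similarity = 0.8) {
  abort_if(length(models) < 2, "need at least two partition models")
  models <- models[order(vapply(models, `[[`, integer(1), "k"))]
  ks <- vapply(models, `[[`, integer(1), "k")

  nodes <- purrr::map2_dfr(models, ks, function(m, k) {
    tibble::tibble(k = k, state = seq_len(m$k))
  })
  node_id <- function(k, state) paste0("k", k, "s", state)

  edges <- purrr::map_dfr(seq_len(length(models) - 1), function(i) {
    a <- models[[i]]
    b <- models[[i + 1]]
    sim <- stats::cor(t(a$centroids), t(b$centroids))
    hit <- which(sim >= min_similarity, arr.ind = TRUE)
    if (nrow(hit) == 0) return(tibble::tibble())
    tibble::tibble(k_a = ks[i], state_a = hit[, 1],
                   k_b = ks[i + 1], state_b = hit[, 2],
                   similarity = sim[hit])
  })

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(node_id(nodes$k, nodes$state))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(node_id(edges$k_a, edges$state_a),
                                    node_id(edges$k_b, edges$state_b)))
  }
  comp <- igraph::components(g)$membership
  families <- dplyr::mutate(nodes,
                            family = unname(comp[node_id(.data$k, .data$state)]))
  structure(list(edges = edges, families = families,
                 min_similarity = min_similarity),
            class = "pl_crossk")
}

#' Split a centroid into its two phase communities
#'
#' The smallest community is the set of regions with positive elements (the
#' sign convention guarantees they are the minority); the largest community
#' is the rest. Element magnitudes are returned as membership strengths. A
#' centroid with no positive element (a global mode, where all signals point
#' the same way) legally yields an empty smallest community.
#'
#' @param vc a sign-conventioned centroid or eigenvector.
#' @return list with `smallest` and `largest` (integer region indices) and
#'   `strength` (abs(vc)).
#' @export
community_split <- function(vc) {
  abort_if(!is.numeric(vc), "`vc` must be numeric")
  list(smallest = which(vc > 0), largest = which(vc <= 0),
       strength = abs(vc))
}

#' Outer product of a centroid
#'
#' The rank-1 matrix `vc vc'`, whose positive entries mark pairs of regions
#' in the same phase community (the matrix rendering of a state).
#'
#' @param vc a unit-norm centroid.
#' @return an N x N symmetric matrix.
#' @export
centroid_outer_product <- function(vc) {
  abort_if(!is.numeric(vc), "`vc` must be numeric")
  tcrossprod(vc)
}
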