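# shared fixtures, all built in code at load time

# tiny two-state ground truth with clean (zero jitter/noise) signals and a
# long dwell scale, used for recovery checks
gt_clean <- make_ground_truth(
  n_regions = 40, k_true = 2, community_sizes = c(8, 10),
  occupancy_by_group = list(low = c(0.5, 0.5), high = c(0.7, 0.3)),
  dwell_mean = 12, jitter_sd = 0, noise_sd = 0, seed = 3
)

cohort_clean <- simulate_cohort(gt_clean, n_low = 6, n_high = 6,
                                n_volumes = 150, base_seed = 7)
pool_clean <- build_pool(compute_phases(cohort_clean))

hidden_trimmed <- function(cohort, n_trim = 1) {
  nv <- cohort$n_volumes
  unlist(lapply(cohort$hidden_labels, function(z) {
    z[(n_trim + 1):(nv - n_trim)]
  }), use.names = FALSE)
}

# best frame agreement over state permutations (small k only)
label_agreement <- function(labels, hidden, k) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  max(vapply(perms(seq_len(k)), function(p) {
    mean(p[hidden] == labels)
  }, numeric(1)))
}

# brute-force connected components of an edge list (BFS), the oracle for
# suprathreshold component extraction
bfs_components <- function(edges) {
  if (nrow(edges) == 0) return(list())
  nodes <- sort(unique(as.vector(edges)))
  visited <- setNames(rep(FALSE, length(nodes)), nodes)
  adj <- split(c(edges[, 2], edges[, 1]),
               as.character(c(edges[, 1], edges[, 2])))
  comps <- list()
  for (n0 in nodes) {
    if (visited[as.character(n0)]) next
    queue <- n0
    comp <- c()
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      key <- as.character(v)
      if (visited[key]) next
      visited[key] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, adj[[key]])
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}
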