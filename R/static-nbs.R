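# Static functional connectivity and the network-based statistic (NBS):
# edgewise OLS t-tests with nuisance covariates, suprathreshold connected
# components, and FWER control by the permutation distribution of the
# maximal component size (extent, in edges).

#' Static Pearson FC matrix of one subject
#'
#' Correlation of each region pair over the full retained (filtered)
#' recording. The diagonal is set to `NA`: self-correlations are excluded
#' from all analyses.
#'
#' @param filtered regions x frames numeric matrix (band-passed series).
#' @return N x N symmetric correlation matrix with `NA` diagonal.
#' @export
static_fc <- function(filtered) {
  abort_if(!is.matrix(filtered) || ncol(filtered) < 3,
           "need a matrix with at least 3 frames")
  v <- apply(filtered, 1, stats::var)
  abort_if(any(v == 0),
           paste0("zero-variance region(s): ",
                  paste(which(v == 0), collapse = ", ")))
  fc <- stats::cor(t(filtered))
  diag(fc) <- NA_real_
  fc
}

# upper-triangle edge index helpers (column-major order of upper.tri)
edge_index <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# subjects x edges matrix from a list of FC matrices
fc_stack <- function(fc_list) {
  n <- nrow(fc_list[[1]])
  ut <- upper.tri(matrix(0, n, n))
  t(vapply(fc_list, function(m) m[ut], numeric(sum(ut))))
}

#' Edgewise GLM t statistics for a group contrast
#'
#' Ordinary least squares of every edge value on
#' `[intercept, group, covariates]`, returning the t statistic of the group
#' coefficient for every edge. With no covariates this equals the classical
#' pooled-variance two-sample t.
#'
#' @param edges subjects x edges numeric matrix (e.g. from stacking FC
#'   upper triangles).
#' @param group_indicator numeric or two-level vector, one per subject; the
#'   contrast is on this column.
#' @param covariates optional numeric matrix/data frame of nuisance columns
#'   (e.g. gender).
#' @return numeric vector of t values, one per edge.
#' @export
edgewise_glm_t <- function(edges, group_indicator, covariates = NULL) {
  edges <- as.matrix(edges)
  g <- if (is.numeric(group_indicator)) {
    group_indicator
  } else {
    as.numeric(factor(group_indicator)) - 1
  }
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.numeric(cv)) cv <- apply(cv, 2, function(x) {
      as.numeric(factor(x)) - 1
    })
    X <- cbind(X, cv)
  }
  abort_if(nrow(X) != nrow(edges),
           "design and edge matrix disagree on subject count")
  abort_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")
  abort_if(nrow(X) < ncol(X) + 2, "too few subjects for the design")
  glm_t_for_design(edges, X, col = 2L)
}

# t statistics of X[, col] for every column of Y, via one QR of X
glm_t_for_design <- function(Y, X, col) {
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  coef <- qr.coef(qx, Y)                     # p x E
  fitted <- qr.fitted(qx, Y)
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / (n - p)
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * xtxinv[col, col], 0))
  tt <- coef[col, ] / se
  # perfect fits: residual variance at rounding level, t is 0 unless the
  # contrast coefficient itself is non-negligible
  scale <- colSums(Y^2)
  degen <- rss <= 1e-12 * pmax(scale, .Machine$double.xmin)
  big <- abs(coef[col, ]) > 1e-8 * sqrt(pmax(scale, 1) / n)
  tt[degen] <- ifelse(big[degen], sign(coef[col, degen]) * Inf, 0)
  tt[se == 0] <- 0
  unname(tt)
}

#' Connected components of the suprathreshold graph
#'
#' Builds a graph over regions with an edge wherever the edgewise t exceeds
#' the threshold (`tail = "positive"`: t > T; `tail = "negative"`:
#' -t > T) and returns its connected components, largest (most edges)
#' first.
#'
#' @param t_map numeric vector of edge t values, in upper-triangle order.
#' @param n_regions number of regions.
#' @param threshold positive t threshold.
#' @param tail `"positive"` or `"negative"`.
#' @return list of components, each a list with `edges` (m x 2 region index
#'   matrix), `nodes`, `n_edges`, `t` (the edge t values).
#' @export
suprathreshold_components <- function(t_map, n_regions, threshold,
                                      tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  abort_if(threshold <= 0, "`threshold` must be positive")
  idx <- edge_index(n_regions)
  sel <- if (tail == "positive") t_map > threshold else -t_map > threshold
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(list())
  e <- idx[sel, , drop = FALSE]
  tv <- t_map[sel]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[e[, 1]]
  comps <- lapply(split(seq_len(nrow(e)), comp_of_edge), function(rows) {
    ed <- e[rows, , drop = FALSE]
    list(edges = ed, nodes = sort(unique(as.vector(ed))),
         n_edges = nrow(ed), t = tv[rows])
  })
  comps[order(-vapply(comps, `[[`, numeric(1), "n_edges"))]
}

# size (in edges) of the largest connected component of a suprathreshold
# edge list, by union-find; the permutation-loop workhorse
max_component_size <- function(e) {
  if (nrow(e) == 0) return(0L)
  nodes <- unique(as.vector(e))
  parent <- seq_along(nodes)
  id <- match(as.vector(e), nodes)
  a <- id[seq_len(nrow(e))]
  b <- id[-seq_len(nrow(e))]
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_len(nrow(e))) {
    ra <- find(a[j])
    rb <- find(b[j])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  edge_root <- vapply(a, find, integer(1))
  max(tabulate(edge_root))
}

#' Network-based statistic
#'
#' Scores each observed suprathreshold component by its extent (edge count)
#' and assigns it a family-wise-error-corrected p value from the permutation
#' distribution of the maximal component size: group labels are permuted
#' (covariate columns held fixed), the edgewise GLM re-fit, and the largest
#' suprathreshold component recorded. The add-one estimator keeps p above 0.
#'
#' @param fc_list list of per-subject FC matrices (from [static_fc()]), or a
#'   subjects x edges matrix with attribute-free upper-triangle ordering
#'   passed together with `n_regions`.
#' @param group_indicator,covariates as in [edgewise_glm_t()].
#' @param threshold t threshold (default 3.5).
#' @param tail `"positive"` or `"negative"` (tested in separate runs).
#' @param n_perm permutations (default 10000).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param seed integer seed.
#' @param n_regions required when `fc_list` is already a stacked matrix.
#' @return an `nbs_result`: list with `components` (as in
#'   [suprathreshold_components()] plus `p_fwer` each), `null_max_sizes`,
#'   `threshold`, `tail`, `t_map`, `n_regions`, `alpha`, `n_perm`, `seed`.
#' @export
nbs <- function(fc_list, group_indicator, covariates = NULL,
                threshold = 3.5, tail = c("positive", "negative"),
                n_perm = 10000, alpha = 0.05, seed = 1L, n_regions = NULL) {
  tail <- match.arg(tail)
  if (is.list(fc_list)) {
    n_regions <- nrow(fc_list[[1]])
    Y <- fc_stack(fc_list)
  } else {
    abort_if(is.null(n_regions),
             "`n_regions` is required with a pre-stacked edge matrix")
    Y <- as.matrix(fc_list)
  }
  g <- if (is.numeric(group_indicator)) {
    group_indicator
  } else {
    as.numeric(factor(group_indicator)) - 1
  }
  X <- cbind(1, g)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.numeric(cv)) cv <- apply(cv, 2, function(x) {
      as.numeric(factor(x)) - 1
    })
    X <- cbind(X, cv)
  }
  abort_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")

  t_obs <- glm_t_for_design(Y, X, col = 2L)
  comps <- suprathreshold_components(t_obs, n_regions, threshold, tail)
  idx <- edge_index(n_regions)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Xp <- X
      Xp[, 2] <- X[sample(nrow(X)), 2]
      tp <- glm_t_for_design(Y, Xp, col = 2L)
      sel <- if (tail == "positive") tp > threshold else -tp > threshold
      sel[is.na(sel)] <- FALSE
      max_component_size(idx[sel, , drop = FALSE])
    }, numeric(1))
  })

  for (i in seq_along(comps)) {
    comps[[i]]$p_fwer <- (1 + sum(null_max >= comps[[i]]$n_edges)) /
      (1 + n_perm)
  }
  structure(
    list(components = comps, null_max_sizes = null_max,
         threshold = threshold, tail = tail, t_map = t_obs,
         n_regions = n_regions, alpha = alpha, n_perm = n_perm,
         seed = as.integer(seed)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> T = %g (%s tail), %d permutations\n",
              x$threshold, x$tail, x$n_perm))
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      cm <- x$components[[i]]
      cat(sprintf("  component %d: %d links between %d regions, p-FWER = %.4g\n",
                  i, cm$n_edges, length(cm$nodes), cm$p_fwer))
    }
  }
  invisible(x)
}

#' Node degrees within a component
#'
#' @param component one element of an `nbs_result`'s `components`.
#' @return tibble: node, degree (edge count at that node within the
#'   component), sorted by decreasing degree.
#' @export
degree_per_node <- function(component) {
  abort_if(is.null(component$edges), "not a component (no `edges`)")
  deg <- table(as.vector(component$edges))
  tibble::tibble(node = as.integer(names(deg)),
                 degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}
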