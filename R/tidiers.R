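# broom-style tidiers for the package's fitted objects

#' Tidy a partition model
#'
#' @param x a `pl_partition`.
#' @param ... unused.
#' @return tibble with one row per state: state, n_frames, share (% of pool
#'   frames), smallest_community_size.
#' @export
tidy.pl_partition <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$k),
    n_frames = x$sizes,
    share = 100 * x$sizes / length(x$labels),
    smallest_community_size = apply(x$centroids, 1, function(v) sum(v > 0))
  )
}

#' @rdname tidy.pl_partition
#' @export
glance.pl_partition <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, metric = x$metric,
                 n_frames = length(x$labels), seed = x$seed)
}

#' Tidy an NBS result
#'
#' @param x an `nbs_result`.
#' @param ... unused.
#' @return tibble with one row per suprathreshold edge: component,
#'   region_a, region_b, t.
#' @export
tidy.nbs_result <- function(x, ...) {
  if (length(x$components) == 0) {
    return(tibble::tibble(component = integer(), region_a = integer(),
                          region_b = integer(), t = numeric()))
  }
  purrr::imap_dfr(x$components, function(cm, i) {
    tibble::tibble(component = i, region_a = cm$edges[, 1],
                   region_b = cm$edges[, 2], t = cm$t)
  })
}

#' @rdname tidy.nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, tail = x$tail,
    n_components = length(x$components),
    largest_n_edges = if (length(x$components)) {
      x$components[[1]]$n_edges
    } else {
      0L
    },
    min_p_fwer = if (length(x$components)) {
      min(vapply(x$components, `[[`, numeric(1), "p_fwer"))
    } else {
      NA_real_
    },
    n_perm = x$n_perm, seed = x$seed
  )
}

#' Tidy a dynamic-arm report
#'
#' @param x a `pl_dynamic_report`.
#' @param ... unused.
#' @return the full comparisons tibble (k, state, metric, t, p_perm, p_fdr,
#'   g, family, group summaries).
#' @export
tidy.pl_dynamic_report <- function(x, ...) x$comparisons

#' @rdname tidy.pl_dynamic_report
#' @export
glance.pl_dynamic_report <- function(x, ...) {
  tibble::tibble(
    headline_k = x$headline_k,
    n_significant = sum(x$comparisons$p_fdr < x$settings$alpha,
                        na.rm = TRUE),
    n_robust_families = nrow(x$robust_families),
    n_perm = x$settings$n_perm, seed = x$settings$seed
  )
}
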