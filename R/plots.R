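# ggplot2 views of the main result types

#' Bar-plot the centroids of a partition model
#'
#' One horizontal bar per region per state, the standard rendering of
#' phase-locking state centroids: positive elements (the smallest, most
#' interpretable community) stand out against the negative majority.
#'
#' @param object a `pl_partition`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pl_partition <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(object$k), function(s) {
    tibble::tibble(state = s, region = seq_len(ncol(object$centroids)),
                   value = object$centroids[s, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value,
                                   fill = .data$value > 0)) +
    ggplot2::geom_col(show.legend = FALSE, width = 1) +
    ggplot2::facet_wrap(~state, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2c3e50")) +
    ggplot2::labs(x = "region", y = "centroid element",
                  title = sprintf("PL state centroids (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot state occupancy or lifetime by group
#'
#' @param profiles tibble from [state_profiles()].
#' @param subjects subjects tibble with `group`.
#' @param metric `"occupancy"` or `"lifetime"`.
#' @return a ggplot (per-state boxplots with jittered subject points).
#' @export
plot_state_metric <- function(profiles, subjects, metric = "occupancy") {
  df <- dplyr::left_join(profiles, subjects, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state),
                                   y = .data[[metric]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "PL state", y = metric) +
    ggplot2::theme_minimal()
}

#' Heatmap of mean transition probabilities per group
#'
#' @param transitions tibble from [transition_profiles()].
#' @param subjects subjects tibble with `group`.
#' @return a ggplot (one facet per group).
#' @export
plot_transition_matrix <- function(transitions, subjects) {
  df <- dplyr::left_join(transitions, subjects, by = "subject_id") |>
    dplyr::group_by(.data$group, .data$from, .data$to) |>
    dplyr::summarise(probability = mean(.data$probability, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_y_reverse(breaks = unique(df$from)) +
    ggplot2::scale_x_continuous(breaks = unique(df$to)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "to state", y = "from state") +
    ggplot2::theme_minimal()
}

#' Plot an NBS result
#'
#' Histogram of the permutation null of the maximal component size, with
#' the observed component sizes marked.
#'
#' @param object an `nbs_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nbs_result <- function(object, ...) {
  df <- tibble::tibble(size = object$null_max_sizes)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::labs(x = "max component size (edges) under permutation",
                  y = "count",
                  title = sprintf("NBS null, T = %g (%s tail)",
                                  object$threshold, object$tail)) +
    ggplot2::theme_minimal()
  if (length(object$components) > 0) {
    obs <- vapply(object$components, `[[`, numeric(1), "n_edges")
    p <- p + ggplot2::geom_vline(xintercept = obs, colour = "#c0392b",
                                 linetype = 2)
  }
  p
}

#' Significance map across partition models
#'
#' Shows which (k, state) pairs differ between groups after FDR, coloured
#' by cross-k family, mirroring the usual consistency display of a k sweep.
#'
#' @param object a `pl_dynamic_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pl_dynamic_report <- function(object, ...) {
  df <- object$comparisons |>
    dplyr::group_by(.data$k, .data$state, .data$family) |>
    dplyr::summarise(significant = any(.data$p_fdr < object$settings$alpha,
                                       na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$state)) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                       ggplot2::aes(fill = factor(.data$family)),
                       colour = "white") +
    ggplot2::geom_tile(data = dplyr::filter(df, !.data$significant),
                       fill = "grey92", colour = "white") +
    ggplot2::labs(x = "partition model (k)", y = "state (by index)",
                  fill = "family") +
    ggplot2::theme_minimal()
}
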