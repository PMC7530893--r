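# Per-subject occupancy, lifetime and transition profiles of state label
# sequences.

check_labels <- function(labels, k) {
  abort_if(length(labels) == 0, "empty label sequence")
  abort_if(anyNA(labels), "labels contain NA")
  abort_if(any(labels < 1 | labels > k), "labels must lie in 1..k")
  invisible(labels)
}

#' Percentage of occupancy per state
#'
#' Fraction of frames assigned to each state, times 100.
#'
#' @param labels integer state sequence (values in 1..k).
#' @param k number of states.
#' @return numeric length-k vector summing to 100.
#' @examples
#' occupancy(c(1, 1, 2, 2), k = 2)
#' @export
occupancy <- function(labels, k) {
  check_labels(labels, k)
  100 * tabulate(labels, k) / length(labels)
}

#' Mean lifetime per state, in seconds
#'
#' Mean length of maximal runs of consecutive frames in the same state,
#' scaled by the repetition time. Runs touching the first or last frame are
#' counted as observed (no censoring). States never visited get `NA`, not
#' zero: absence is not brevity.
#'
#' @param labels integer state sequence.
#' @param k number of states.
#' @param tr repetition time in seconds.
#' @return list with `lifetime` (seconds, length k, `NA` where unvisited)
#'   and `n_visits` (run counts).
#' @examples
#' mean_lifetime(c(1, 1, 1, 2), k = 2, tr = 2)
#' @export
mean_lifetime <- function(labels, k, tr) {
  check_labels(labels, k)
  abort_if(tr <= 0, "`tr` must be positive")
  r <- rle(labels)
  lt <- rep(NA_real_, k)
  nv <- integer(k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    nv[s] <- length(runs)
    if (nv[s] > 0) lt[s] <- mean(runs) * tr
  }
  list(lifetime = lt, n_visits = nv)
}

#' Transition probabilities between states
#'
#' Counts transitions over consecutive frame pairs of one subject's label
#' sequence and row-normalizes by outgoing count. With
#' `include_self = FALSE` the diagonal is removed before normalization, so
#' rows give the probability of switching to each other state conditional on
#' leaving. Rows of never-left (or never-visited) states are `NA`, not
#' zero-filled.
#'
#' @param labels integer state sequence (at least 2 frames).
#' @param k number of states.
#' @param include_self keep self-transitions (default `TRUE`).
#' @return list with `matrix` (k x k row-stochastic, NA rows where
#'   undefined) and `counts` (k x k integer).
#' @examples
#' transition_profile(c(1, 2, 1, 2), k = 2, include_self = FALSE)
#' @export
transition_profile <- function(labels, k, include_self = TRUE) {
  check_labels(labels, k)
  abort_if(length(labels) < 2, "need at least 2 frames")
  from <- labels[-length(labels)]
  to <- labels[-1]
  counts <- matrix(0L, k, k)
  for (i in seq_along(from)) {
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  m <- counts
  if (!include_self) diag(m) <- 0L
  p <- matrix(NA_real_, k, k)
  rs <- rowSums(m)
  ok <- rs > 0
  p[ok, ] <- m[ok, , drop = FALSE] / rs[ok]
  list(matrix = p, counts = counts)
}

#' Per-subject state profiles for one partition model
#'
#' Splits the partition's pooled labels back into subjects and computes each
#' subject's occupancy, mean lifetime and visit counts per state.
#'
#' @param partition a `pl_partition` carrying a pool index.
#' @param tr repetition time in seconds.
#' @return tibble: subject_id, state, occupancy (%), lifetime (s, `NA` when
#'   never visited), n_visits.
#' @export
state_profiles <- function(partition, tr) {
  stopifnot(inherits(partition, "pl_partition"))
  abort_if(is.null(partition$index),
           "partition lacks a pool index; cluster a `pl_pool`")
  k <- partition$k
  df <- dplyr::mutate(partition$index, label = partition$labels)
  df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      occ <- occupancy(d$label, k)
      lt <- mean_lifetime(d$label, k, tr)
      tibble::tibble(state = seq_len(k), occupancy = occ,
                     lifetime = lt$lifetime, n_visits = lt$n_visits)
    }) |>
    dplyr::ungroup()
}

#' Per-subject transition profiles for one partition model
#'
#' @param partition a `pl_partition` carrying a pool index.
#' @param include_self keep self-transitions (default `TRUE`).
#' @return tibble: subject_id, from, to, probability, count. Transitions are
#'   counted within each subject only; no pair straddles two subjects.
#' @export
transition_profiles <- function(partition, include_self = TRUE) {
  stopifnot(inherits(partition, "pl_partition"))
  abort_if(is.null(partition$index),
           "partition lacks a pool index; cluster a `pl_pool`")
  k <- partition$k
  df <- dplyr::mutate(partition$index, label = partition$labels)
  df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      tp <- transition_profile(d$label, k, include_self = include_self)
      tibble::tibble(from = rep(seq_len(k), k),
                     to = rep(seq_len(k), each = k),
                     probability = as.vector(tp$matrix),
                     count = as.vector(tp$counts))
    }) |>
    dplyr::ungroup()
}
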