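# Group-level inference: stratified (gender-restricted) permutation t-tests,
# FDR adjustment, effect sizes, demographics and motion QC.

pooled_t_stat <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  v1 <- if (n1 > 1) stats::var(x1) else 0   # singleton contributes no df
  v2 <- if (n2 > 1) stats::var(x2) else 0
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Stratified permutation t-test
#'
#' Two-sided non-parametric test of a group difference based on the pooled
#' two-sample t statistic, with group labels permuted only within strata
#' (e.g. within gender), so a covariate that is imbalanced across groups
#' cannot masquerade as a group effect. The p value uses the add-one
#' (permutation-inclusive) estimator, so it is never exactly 0.
#'
#' @param values numeric vector, one observation per subject. `NA` values
#'   are dropped together with their labels.
#' @param group_labels two-level grouping (character or factor).
#' @param strata_labels stratum per subject (same length); `NULL` for an
#'   unrestricted permutation test.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `t_observed`, `p_perm`, `n_perm`, and per-group `n`,
#'   `mean`, `sd` (named by group level).
#' @examples
#' set.seed(1)
#' perm_ttest_restricted(rnorm(20), rep(c("a", "b"), 10),
#'                       rep(c("F", "M"), each = 10), n_perm = 200, seed = 1)
#' @export
perm_ttest_restricted <- function(values, group_labels, strata_labels = NULL,
                                  n_perm = 10000, seed = 1L) {
  keep <- !is.na(values)
  values <- values[keep]
  group_labels <- as.character(group_labels)[keep]
  strata_labels <- if (is.null(strata_labels)) {
    rep("all", length(values))
  } else {
    as.character(strata_labels)[keep]
  }
  lv <- sort(unique(group_labels))
  abort_if(length(lv) != 2, "need exactly two groups with data")
  g1 <- group_labels == lv[1]

  t_obs <- pooled_t_stat(values[g1], values[!g1])

  strata <- split(seq_along(values), strata_labels)
  singletons <- names(strata)[lengths(strata) < 2]
  if (length(singletons) > 0) {
    warning(sprintf("stratum/strata with a single subject kept fixed: %s",
                    paste(singletons, collapse = ", ")), call. = FALSE)
  }

  exceed <- with_seed(seed, {
    hits <- 0L
    idx_by_stratum <- strata
    for (b in seq_len(n_perm)) {
      perm_g1 <- g1
      for (ix in idx_by_stratum) {
        if (length(ix) >= 2) perm_g1[ix] <- g1[sample(ix)]
      }
      tb <- pooled_t_stat(values[perm_g1], values[!perm_g1])
      if (abs(tb) >= abs(t_obs) - 1e-12) hits <- hits + 1L
    }
    hits
  })

  summ <- lapply(lv, function(l) {
    x <- values[group_labels == l]
    c(n = length(x), mean = mean(x), sd = stats::sd(x))
  })
  names(summ) <- lv
  list(t_observed = t_obs, p_perm = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, groups = summ)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (a thin wrapper over `stats::p.adjust`), applied
#' within one testing family: all k states of one metric in one partition
#' model.
#'
#' @param p_values numeric vector in \[0, 1\] (`NA` allowed and preserved).
#' @return adjusted p values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  abort_if(any(p_values < 0 | p_values > 1, na.rm = TRUE),
           "p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hedges' g from group summaries
#'
#' Standardized mean difference with the (n-1)-weighted pooled SD. The
#' default omits the small-sample correction factor
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`; set
#' `small_sample_correction = TRUE` to apply it.
#'
#' @param n1,mean1,sd1 first group's size, mean, SD.
#' @param n2,mean2,sd2 second group's size, mean, SD.
#' @param small_sample_correction apply the J factor (default `FALSE`).
#' @return the effect size (sign follows `mean1 - mean2`).
#' @examples
#' hedges_g(19, 16.1, 8.8, 50, 9.8, 8.0) # ~0.77
#' @export
hedges_g <- function(n1, mean1, sd1, n2, mean2, sd2,
                     small_sample_correction = FALSE) {
  abort_if(n1 < 2 || n2 < 2, "both groups need n >= 2")
  abort_if(sd1 < 0 || sd2 < 0, "SDs must be non-negative")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  abort_if(sp == 0, "pooled SD is zero; effect size undefined")
  g <- (mean1 - mean2) / sp
  if (small_sample_correction) g <- g * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  g
}

#' Pearson chi-square test of a 2 x 2 table
#'
#' Without continuity correction, df = 1. Used for demographic comparisons
#' such as the women/men split across groups.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chi2_2x2(matrix(c(16, 21, 3, 29), 2)) # ~9.9
#' @export
chi2_2x2 <- function(table) {
  abort_if(!is.matrix(table) || any(dim(table) != 2),
           "`table` must be a 2 x 2 matrix")
  abort_if(any(table < 0), "counts must be non-negative")
  abort_if(any(rowSums(table) == 0) || any(colSums(table) == 0),
           "all margins must be positive")
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Framewise displacement from realignment parameters
#'
#' FD(t) is the sum of absolute backward differences of the six rigid-body
#' parameters, with rotations (radians) converted to arc length on a sphere
#' of the given radius. The mean is over frames 2..T.
#'
#' @param motion_params T x 6 matrix or data frame: three translations (mm)
#'   then three rotations (radians).
#' @param rotation_radius_mm sphere radius for the rotation arc (default 50).
#' @return list with `fd_trace` (length T-1) and `mean_fd`.
#' @export
mean_fd <- function(motion_params, rotation_radius_mm = 50) {
  mp <- as.matrix(motion_params)
  abort_if(ncol(mp) != 6, "motion parameters must have 6 columns")
  abort_if(nrow(mp) < 2, "need at least 2 frames")
  d <- abs(diff(mp))
  d[, 4:6] <- d[, 4:6] * rotation_radius_mm
  fd <- rowSums(d)
  list(fd_trace = fd, mean_fd = mean(fd))
}

#' Compare a state metric between groups across all states of one model
#'
#' Runs the stratified permutation t-test per state on one column of a
#' [state_profiles()] table, then BH-adjusts the k p values as one family.
#' Subjects with `NA` for a state (e.g. lifetime of a never-visited state)
#' are excluded from that state's test.
#'
#' @param profiles tibble from [state_profiles()].
#' @param subjects subjects tibble with `subject_id`, `group` and the strata
#'   column.
#' @param metric `"occupancy"` or `"lifetime"` (a column of `profiles`).
#' @param strata name of the strata column in `subjects` (default
#'   `"gender"`; `NULL` disables stratification).
#' @param n_perm,seed permutation settings.
#' @return tibble: state, metric, t_observed, p_perm, p_fdr, g, and
#'   per-group n/mean/sd columns. `g` is group difference (high minus low
#'   when the levels are low/high; otherwise first minus second level) in
#'   pooled-SD units, uncorrected.
#' @export
compare_states <- function(profiles, subjects, metric = "occupancy",
                           strata = "gender", n_perm = 10000, seed = 1L) {
  abort_if(!metric %in% names(profiles),
           sprintf("metric '%s' is not a column of `profiles`", metric))
  abort_if(length(unique(subjects$group)) != 2,
           "group comparison needs exactly two groups")
  df <- dplyr::left_join(profiles, subjects, by = "subject_id")
  lv <- sort(unique(as.character(df$group)))
  # report effects as high - low when those labels are used
  if (setequal(lv, c("high", "low"))) lv <- c("high", "low")
  seeds <- derive_seeds(seed, max(df$state))
  res <- df |>
    dplyr::group_by(.data$state) |>
    dplyr::group_modify(function(d, key) {
      vals <- d[[metric]]
      st <- if (is.null(strata)) NULL else d[[strata]]
      # force the reported sign to lv[1] - lv[2]
      grp <- factor(as.character(d$group), levels = lv)
      keep <- !is.na(vals)
      g1 <- vals[keep][grp[keep] == lv[1]]
      g2 <- vals[keep][grp[keep] == lv[2]]
      pt <- perm_ttest_restricted(vals, as.character(grp), st,
                                  n_perm = n_perm, seed = seeds[key$state])
      t_obs <- pooled_t_stat(g1, g2)
      g_eff <- tryCatch(
        hedges_g(length(g1), mean(g1), stats::sd(g1),
                 length(g2), mean(g2), stats::sd(g2)),
        error = function(e) NA_real_
      )
      tibble::tibble(
        metric = metric, t_observed = t_obs, p_perm = pt$p_perm, g = g_eff,
        n_1 = length(g1), mean_1 = mean(g1), sd_1 = stats::sd(g1),
        n_2 = length(g2), mean_2 = mean(g2), sd_2 = stats::sd(g2),
        group_1 = lv[1], group_2 = lv[2], n_perm = n_perm,
        seed = seeds[key$state]
      )
    }) |>
    dplyr::ungroup()
  dplyr::mutate(res, p_fdr = fdr_bh(.data$p_perm),
                .after = "p_perm")
}

#' Compare every transition probability between groups
#'
#' One stratified permutation test per (from, to) cell of the subject-level
#' transition matrices, reported at uncorrected p (each cell its own test).
#'
#' @param transitions tibble from [transition_profiles()].
#' @param subjects subjects tibble.
#' @param strata,n_perm,seed as in [compare_states()].
#' @return tibble: from, to, t_observed, p_perm, g.
#' @export
compare_transitions <- function(transitions, subjects, strata = "gender",
                                n_perm = 10000, seed = 1L) {
  df <- dplyr::left_join(transitions, subjects, by = "subject_id")
  lv <- sort(unique(as.character(df$group)))
  if (setequal(lv, c("high", "low"))) lv <- c("high", "low")
  cells <- dplyr::distinct(df, .data$from, .data$to)
  seeds <- derive_seeds(seed, nrow(cells))
  purrr::pmap_dfr(
    list(cells$from, cells$to, seeds),
    function(f, t, s) {
      d <- dplyr::filter(df, .data$from == f, .data$to == t)
      vals <- d$probability
      if (sum(!is.na(vals)) < 4 ||
          length(unique(d$group[!is.na(vals)])) < 2) {
        return(tibble::tibble(from = f, to = t, t_observed = NA_real_,
                              p_perm = NA_real_, g = NA_real_))
      }
      st <- if (is.null(strata)) NULL else d[[strata]]
      pt <- perm_ttest_restricted(vals, as.character(d$group), st,
                                  n_perm = n_perm, seed = s)
      keep <- !is.na(vals)
      grp <- factor(as.character(d$group), levels = lv)
      g1 <- vals[keep][grp[keep] == lv[1]]
      g2 <- vals[keep][grp[keep] == lv[2]]
      g_eff <- tryCatch(
        hedges_g(length(g1), mean(g1), stats::sd(g1),
                 length(g2), mean(g2), stats::sd(g2)),
        error = function(e) NA_real_
      )
      tibble::tibble(from = f, to = t,
                     t_observed = pooled_t_stat(g1, g2),
                     p_perm = pt$p_perm, g = g_eff)
    }
  )
}
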