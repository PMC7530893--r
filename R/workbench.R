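# End-to-end orchestration of the dynamic (LEiDA) and static (NBS) arms,
# group classification and motion QC.

#' Split subjects into groups by a questionnaire score
#'
#' Scores above the cutoff are labelled `"high"`, scores at or below it
#' `"low"` (the conventional depression-inventory cutoff is 20). Subjects
#' with missing scores are dropped with a message.
#'
#' @param metadata data frame with one row per subject.
#' @param score_column name of the numeric score column.
#' @param cutoff threshold (default 20).
#' @return `metadata` with a `group` column added (rows with missing scores
#'   removed).
#' @examples
#' classify_groups(data.frame(subject_id = 1:3, mdi = c(29, 7, 20)), "mdi")
#' @export
classify_groups <- function(metadata, score_column, cutoff = 20) {
  abort_if(!score_column %in% names(metadata),
           sprintf("column '%s' not found", score_column))
  sc <- metadata[[score_column]]
  abort_if(!is.numeric(sc), "scores must be numeric")
  miss <- is.na(sc)
  if (any(miss)) {
    message(sprintf("dropping %d subject(s) with missing scores", sum(miss)))
    metadata <- metadata[!miss, , drop = FALSE]
    sc <- sc[!miss]
  }
  dplyr::mutate(tibble::as_tibble(metadata),
                group = ifelse(sc > cutoff, "high", "low"))
}

#' Run the dynamic (phase-locking states) arm
#'
#' Filter -> phases -> trim -> leading eigenvectors -> k sweep -> per-subject
#' profiles -> stratified permutation tests with per-model FDR -> cross-k
#' state families. Deterministic given the seeds in `cohort` and `seed`.
#'
#' @param cohort a `pl_cohort` with a two-group `subjects` table.
#' @param k_min,k_max partition-model sweep bounds (defaults 4 and 14).
#' @param low_hz,high_hz,order,n_trim filtering/trimming settings.
#' @param n_init,max_iter,metric clustering settings.
#' @param n_perm,strata permutation-test settings (strata default
#'   `"gender"`).
#' @param alpha significance level for flagging (default 0.05).
#' @param min_models a cross-k family must be significant in at least this
#'   many partition models to be reported as robust (default 3).
#' @param seed integer seed driving clustering restarts and permutations.
#' @return a `pl_dynamic_report`: list with `comparisons` (tibble over all
#'   k, states and metrics), `families`, `robust_families`, `headline_k`,
#'   `sweep`, `pool`, `profiles` (per-k list), `transitions` (headline k),
#'   `settings`.
#' @export
run_dynamic_arm <- function(cohort, k_min = 4, k_max = 14,
                            low_hz = 0.01, high_hz = 0.1, order = 9,
                            n_trim = 1, n_init = 50, max_iter = 500,
                            metric = "cosine", n_perm = 10000,
                            strata = "gender", alpha = 0.05,
                            min_models = 3, seed = 1L) {
  stopifnot(inherits(cohort, "pl_cohort"))
  abort_if(length(unique(cohort$subjects$group)) != 2,
           "the dynamic arm needs exactly two groups")
  phases <- compute_phases(cohort, low_hz = low_hz, high_hz = high_hz,
                           order = order, n_trim = n_trim)
  pool <- build_pool(phases)
  sw <- sweep_k(pool, k_min = k_min, k_max = k_max, n_init = n_init,
                max_iter = max_iter, seed = seed, metric = metric)

  seeds <- derive_seeds(seed + 1, length(sw) * 2)
  profiles <- list()
  comparisons <- purrr::imap_dfr(sw, function(model, nm) {
    prof <- state_profiles(model, tr = cohort$tr)
    profiles[[nm]] <<- prof
    i <- match(nm, names(sw))
    occ <- compare_states(prof, cohort$subjects, "occupancy",
                          strata = strata, n_perm = n_perm,
                          seed = seeds[2 * i - 1])
    lt <- compare_states(prof, cohort$subjects, "lifetime",
                         strata = strata, n_perm = n_perm,
                         seed = seeds[2 * i])
    dplyr::mutate(dplyr::bind_rows(occ, lt), k = model$k, .before = 1)
  })

  fams <- if (length(sw) >= 2) {
    match_states_across_k(sw)
  } else {
    # single partition model: every state is its own family
    m <- sw[[1]]
    structure(list(edges = tibble::tibble(),
                   families = tibble::tibble(k = m$k,
                                             state = seq_len(m$k),
                                             family = seq_len(m$k)),
                   min_similarity = NA_real_),
              class = "pl_crossk")
  }
  comparisons <- dplyr::left_join(comparisons, fams$families,
                                  by = c("k", "state"))

  sig <- dplyr::filter(comparisons, .data$p_fdr < alpha)
  robust <- sig |>
    dplyr::distinct(.data$family, .data$k) |>
    dplyr::count(.data$family, name = "n_models") |>
    dplyr::filter(.data$n_models >= min_models)

  # headline model: the k capturing the most significant (state, metric)
  # pairs after FDR; ties toward smaller k
  headline_k <- if (nrow(sig) > 0) {
    tallies <- dplyr::count(sig, .data$k)
    min(tallies$k[tallies$n == max(tallies$n)])
  } else {
    NA_integer_
  }
  transitions <- if (!is.na(headline_k)) {
    transition_profiles(sw[[paste0("k", headline_k)]])
  } else {
    NULL
  }

  structure(
    list(comparisons = comparisons, families = fams,
         robust_families = robust, headline_k = headline_k,
         sweep = sw, pool = pool, profiles = profiles,
         transitions = transitions,
         settings = list(k_min = k_min, k_max = k_max, n_perm = n_perm,
                         n_init = n_init, metric = metric, strata = strata,
                         alpha = alpha, min_models = min_models,
                         seed = seed)),
    class = "pl_dynamic_report"
  )
}

#' @export
print.pl_dynamic_report <- function(x, ...) {
  ns <- sum(x$comparisons$p_fdr < x$settings$alpha, na.rm = TRUE)
  cat(sprintf("<pl_dynamic_report> k = %d..%d, %d significant (p-FDR < %g) state-metric pairs\n",
              x$settings$k_min, x$settings$k_max, ns, x$settings$alpha))
  if (!is.na(x$headline_k)) {
    cat(sprintf("  headline partition model: k = %d\n", x$headline_k))
  }
  if (nrow(x$robust_families) > 0) {
    cat(sprintf("  robust cross-k families (>= %d models): %s\n",
                x$settings$min_models,
                paste(x$robust_families$family, collapse = ", ")))
  }
  invisible(x)
}

#' Run the static (NBS) arm
#'
#' Band-pass filter -> per-subject Pearson FC -> edgewise GLM t with a
#' gender covariate -> suprathreshold components at each threshold and tail
#' -> FWER p by max-component-size permutation.
#'
#' @param cohort a `pl_cohort`.
#' @param thresholds t thresholds to sweep (default `c(3.1, 3.5, 4)`).
#' @param tails tails to test separately (default both).
#' @param covariate column of `cohort$subjects` used as nuisance regressor
#'   (default `"gender"`; `NULL` for none).
#' @param low_hz,high_hz,order filter settings.
#' @param n_perm,alpha,seed NBS settings.
#' @return a `pl_static_report`: list with `results` (named list of
#'   `nbs_result` per threshold/tail), `summary` tibble, `settings`.
#' @export
run_static_arm <- function(cohort, thresholds = c(3.1, 3.5, 4),
                           tails = c("positive", "negative"),
                           covariate = "gender",
                           low_hz = 0.01, high_hz = 0.1, order = 9,
                           n_perm = 10000, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cohort, "pl_cohort"))
  if (length(thresholds) == 0) {
    return(structure(list(results = list(),
                          summary = tibble::tibble(),
                          settings = list(thresholds = thresholds)),
                     class = "pl_static_report"))
  }
  filtered <- purrr::map(cohort$series, bandpass, tr = cohort$tr,
                         low_hz = low_hz, high_hz = high_hz, order = order)
  fc <- purrr::map(filtered, static_fc)
  covs <- if (is.null(covariate)) NULL else cohort$subjects[[covariate]]
  combos <- expand.grid(threshold = thresholds, tail = tails,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  results <- purrr::pmap(
    list(combos$threshold, combos$tail, seeds),
    function(th, tl, s) {
      nbs(fc, cohort$subjects$group, covariates = covs, threshold = th,
          tail = tl, n_perm = n_perm, alpha = alpha, seed = s)
    }
  )
  names(results) <- sprintf("T%g_%s", combos$threshold, combos$tail)
  summary <- purrr::imap_dfr(results, function(r, nm) {
    if (length(r$components) == 0) {
      return(tibble::tibble(run = nm, threshold = r$threshold,
                            tail = r$tail, component = NA_integer_,
                            n_edges = 0L, n_nodes = 0L, p_fwer = NA_real_))
    }
    purrr::imap_dfr(r$components, function(cm, i) {
      tibble::tibble(run = nm, threshold = r$threshold, tail = r$tail,
                     component = i, n_edges = cm$n_edges,
                     n_nodes = length(cm$nodes), p_fwer = cm$p_fwer)
    })
  })
  structure(
    list(results = results, summary = summary,
         settings = list(thresholds = thresholds, tails = tails,
                         covariate = covariate, n_perm = n_perm,
                         alpha = alpha, seed = seed)),
    class = "pl_static_report"
  )
}

#' @export
print.pl_static_report <- function(x, ...) {
  cat(sprintf("<pl_static_report> %d threshold/tail runs\n",
              length(x$results)))
  if (nrow(x$summary) > 0) print(x$summary)
  invisible(x)
}

#' Motion quality control
#'
#' Compares mean framewise displacement between groups (two-sample t-test)
#' and correlates per-subject mean FD with each headline state's occupancy
#' and lifetime.
#'
#' @param fd tibble with `subject_id` and `mean_fd` (e.g. from applying
#'   [mean_fd()] per subject).
#' @param subjects subjects tibble with `group`.
#' @param profiles a [state_profiles()] tibble for the headline model
#'   (optional).
#' @param states states to correlate against (default: all in `profiles`).
#' @return list with `group_test` (tibble) and `metric_correlations`
#'   (tibble, possibly empty).
#' @export
qc_motion <- function(fd, subjects, profiles = NULL, states = NULL) {
  abort_if(!all(c("subject_id", "mean_fd") %in% names(fd)),
           "`fd` needs subject_id and mean_fd columns")
  df <- dplyr::inner_join(fd, subjects, by = "subject_id")
  abort_if(length(unique(df$group)) != 2, "need two groups with FD data")
  gt <- tryCatch(stats::t.test(mean_fd ~ group, data = df),
                 error = function(e) NULL)
  group_test <- if (is.null(gt)) {
    # essentially constant FD: no group difference to test
    tibble::tibble(statistic = NA_real_, p = NA_real_,
                   mean_1 = mean(df$mean_fd), mean_2 = mean(df$mean_fd))
  } else {
    tibble::tibble(
      statistic = unname(gt$statistic), p = gt$p.value,
      mean_1 = unname(gt$estimate[1]), mean_2 = unname(gt$estimate[2])
    )
  }
  metric_correlations <- tibble::tibble()
  if (!is.null(profiles)) {
    states <- states %||% sort(unique(profiles$state))
    long <- profiles |>
      dplyr::filter(.data$state %in% states) |>
      tidyr::pivot_longer(c("occupancy", "lifetime"), names_to = "metric",
                          values_to = "value") |>
      dplyr::inner_join(fd, by = "subject_id")
    metric_correlations <- long |>
      dplyr::group_by(.data$state, .data$metric) |>
      dplyr::group_modify(function(d, key) {
        ok <- stats::complete.cases(d$value, d$mean_fd)
        if (sum(ok) < 3 || stats::sd(d$value[ok]) == 0 ||
            stats::sd(d$mean_fd[ok]) == 0) {
          return(tibble::tibble(r = NA_real_, p = NA_real_,
                                n = sum(ok)))
        }
        ct <- stats::cor.test(d$value[ok], d$mean_fd[ok])
        tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
      }) |>
      dplyr::ungroup()
  }
  list(group_test = group_test, metric_correlations = metric_correlations)
}
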