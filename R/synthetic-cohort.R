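# Synthetic cohorts with planted, Markov-switching phase-locking states.
#
# The generator emulates the statistical structure of a resting-state BOLD
# study: band-limited oscillations, a hidden state sequence per subject, and
# group-level differences in how often (and how long) each state is visited.
# All regions loosely track a common band-limited carrier (each with its own
# mean-reverting phase deviation, so the background is broadly coherent, as
# BOLD signals are); during state s the regions of that state's community
# phase-shift to anti-phase with the carrier (plus jitter), forming the
# minority community that the leading eigenvector's positive elements pick
# out. The observed signal is the cosine of the phase plus Gaussian noise.

#' Define the ground truth of a synthetic cohort
#'
#' Fixes the planted phase-locking states (one community of co-phased regions
#' per state), the per-group stationary occupancy profiles, and the dwell
#' scale of the hidden Markov chain. Defaults mirror a two-group resting-state
#' study: 223 regions, 9 states, a 19-versus-50 group split with one state
#' over-expressed (16.1% vs 9.8%) and one under-expressed (6.2% vs 10.6%) in
#' the high-scoring group, and a 16/3 vs 21/29 women/men composition.
#'
#' The hidden chain is built so that its stationary distribution is exactly
#' the configured occupancy profile: from state s it stays with probability
#' `1 - (1 - pi_s)/d` and otherwise jumps to state t with probability
#' proportional to `pi_t`, where `d` is the scalar `dwell_mean`. Dwell in
#' state s is then geometric with mean `d / (1 - pi_s)` frames (states that
#' are occupied more also persist longer). If `dwell_mean` is a vector, the
#' exit probability of state s is `1/d_s` with jump targets proportional to
#' the occupancy profile; the chain's exact stationary distribution (returned
#' in `realized_occupancy`) then only approximates the configured profile.
#'
#' @param n_regions number of regions (rows of every series matrix).
#' @param k_true number of planted states.
#' @param community_sizes integer vector (length `k_true`) of community
#'   sizes; each must be below `n_regions / 2` so the planted set is always
#'   the smallest of the two phase communities. Default: sizes spread between
#'   roughly 8% and 20% of the regions.
#' @param occupancy_by_group named list of per-group probability vectors over
#'   states (must each sum to 1).
#' @param dwell_mean dwell scale in frames (scalar, default 3) or a per-state
#'   vector of target mean dwells.
#' @param carrier_freq carrier frequency in Hz; must lie inside the
#'   0.01-0.1 Hz analysis band (default 0.05).
#' @param jitter_sd SD (radians) of the per-frame phase jitter of community
#'   members around the common carrier.
#' @param noise_sd SD of additive Gaussian observation noise (signal units).
#' @param background_sd stationary SD (radians) of the mean-reverting phase
#'   deviation of off-community regions around the common carrier.
#' @param background_rho frame-to-frame AR(1) coefficient of that deviation.
#' @param gender_composition named list `list(group = c(n_women, n_men))`.
#' @param gender_occupancy_shift optional size of a planted gender effect:
#'   women's occupancy profile is tilted toward state 1 by this amount
#'   (default 0, gender is a pure nuisance label).
#' @param seed integer seed; the ground truth is reproducible given the seed.
#' @return an object of class `pl_ground_truth`.
#' @examples
#' gt <- make_ground_truth(n_regions = 40, k_true = 2,
#'   occupancy_by_group = list(low = c(0.5, 0.5), high = c(0.7, 0.3)),
#'   seed = 1)
#' lengths(gt$communities)
#' @export
make_ground_truth <- function(n_regions = 223,
                              k_true = 9,
                              community_sizes = NULL,
                              occupancy_by_group = NULL,
                              dwell_mean = 3,
                              carrier_freq = 0.05,
                              jitter_sd = 0.3,
                              noise_sd = 0.2,
                              background_sd = 1.0,
                              background_rho = 0.9,
                              gender_composition = list(low = c(21, 29),
                                                        high = c(16, 3)),
                              gender_occupancy_shift = 0,
                              seed = 1L) {
  abort_if(n_regions < 4, "need at least 4 regions")
  abort_if(k_true < 2, "need at least 2 states")
  if (is.null(occupancy_by_group)) {
    occupancy_by_group <- default_occupancy_profiles(k_true)
  }
  for (g in names(occupancy_by_group)) {
    p <- occupancy_by_group[[g]]
    abort_if(length(p) != k_true,
             sprintf("occupancy profile for group '%s' must have length %d",
                     g, k_true))
    abort_if(any(p < 0) || abs(sum(p) - 1) > 1e-8,
             sprintf("occupancy profile for group '%s' must sum to 1", g))
  }
  if (is.null(community_sizes)) {
    community_sizes <- pmax(3L, round(seq(0.08, 0.2, length.out = k_true) *
                                        n_regions))
  }
  abort_if(length(community_sizes) != k_true,
           "`community_sizes` must have length `k_true`")
  abort_if(any(community_sizes < 1) ||
             any(community_sizes >= n_regions / 2),
           "each community must be non-empty and smaller than half the regions")
  abort_if(carrier_freq <= 0.01 || carrier_freq >= 0.1,
           "`carrier_freq` must lie strictly inside the 0.01-0.1 Hz band")
  abort_if(!length(dwell_mean) %in% c(1L, k_true),
           "`dwell_mean` must be a scalar or one value per state")
  abort_if(any(dwell_mean < 1), "`dwell_mean` must be at least 1 frame")

  communities <- with_seed(seed, {
    repeat {
      cs <- lapply(community_sizes, function(m) sort(sample.int(n_regions, m)))
      ids <- vapply(cs, paste, character(1), collapse = ",")
      if (!anyDuplicated(ids)) break
    }
    cs
  })

  chains <- lapply(occupancy_by_group, build_state_chain,
                   dwell_mean = dwell_mean)

  structure(
    list(n_regions = as.integer(n_regions),
         k_true = as.integer(k_true),
         communities = communities,
         occupancy_profile = occupancy_by_group,
         dwell_mean = dwell_mean,
         realized_dwell = lapply(chains, `[[`, "mean_dwell"),
         realized_occupancy = lapply(chains, `[[`, "stationary"),
         transition = lapply(chains, `[[`, "P"),
         carrier_freq = carrier_freq,
         jitter_sd = jitter_sd,
         noise_sd = noise_sd,
         background_sd = background_sd,
         background_rho = background_rho,
         gender_composition = gender_composition,
         gender_occupancy_shift = gender_occupancy_shift,
         seed = as.integer(seed)),
    class = "pl_ground_truth"
  )
}

# default two-group profiles patterned on a study in which one state is
# over-expressed (16.1% vs 9.8%) and another under-expressed (6.2% vs 10.6%)
# in the high-scoring group; remaining states share the rest uniformly
default_occupancy_profiles <- function(k_true) {
  if (k_true >= 3) {
    up <- c(high = 0.161, low = 0.098)
    dn <- c(high = 0.062, low = 0.106)
    lapply(list(low = "low", high = "high"), function(g) {
      p <- rep((1 - up[[g]] - dn[[g]]) / (k_true - 2), k_true)
      p[1] <- up[[g]]
      p[2] <- dn[[g]]
      p / sum(p)
    })
  } else {
    list(low = rep(1 / k_true, k_true),
         high = c(0.65, rep(0.35 / (k_true - 1), k_true - 1)))
  }
}

# hidden-state Markov chain with self-transitions set by the dwell scale.
# scalar dwell: stationary distribution is exactly `pi`; vector dwell:
# stationary computed from the chain (left unit eigenvector).
build_state_chain <- function(pi, dwell_mean) {
  k <- length(pi)
  P <- matrix(0, k, k)
  if (length(dwell_mean) == 1L) {
    d <- max(dwell_mean, max(1 - pi) + 1e-9)
    for (s in seq_len(k)) {
      P[s, ] <- pi / d
      P[s, s] <- 1 - (1 - pi[s]) / d
    }
    stationary <- pi
  } else {
    for (s in seq_len(k)) {
      out <- pi
      out[s] <- 0
      out <- out / sum(out)
      P[s, ] <- out / dwell_mean[s]
      P[s, s] <- 1 - 1 / dwell_mean[s]
    }
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    stationary <- v / sum(v)
  }
  list(P = P, stationary = stationary, mean_dwell = 1 / (1 - diag(P)))
}

#' @export
print.pl_ground_truth <- function(x, ...) {
  cat(sprintf("<pl_ground_truth> %d regions, %d planted states, carrier %.3g Hz\n",
              x$n_regions, x$k_true, x$carrier_freq))
  cat("  community sizes:", paste(lengths(x$communities), collapse = ", "), "\n")
  for (g in names(x$occupancy_profile)) {
    cat(sprintf("  %s occupancy: %s\n", g,
                paste(sprintf("%.3f", x$occupancy_profile[[g]]), collapse = " ")))
  }
  invisible(x)
}

# sample a hidden state sequence from the group's chain
sample_states <- function(gt, group, n_volumes, woman = FALSE) {
  P <- gt$transition[[group]]
  pi0 <- gt$realized_occupancy[[group]]
  if (woman && gt$gender_occupancy_shift > 0) {
    pi <- gt$occupancy_profile[[group]]
    pi[1] <- pi[1] + gt$gender_occupancy_shift
    pi <- pi / sum(pi)
    ch <- build_state_chain(pi, gt$dwell_mean)
    P <- ch$P
    pi0 <- ch$stationary
  }
  k <- nrow(P)
  z <- integer(n_volumes)
  z[1] <- sample.int(k, 1, prob = pi0)
  for (t in 2:n_volumes) z[t] <- sample.int(k, 1, prob = P[z[t - 1], ])
  z
}

#' Simulate one synthetic subject
#'
#' Draws a hidden state sequence from the group's Markov chain, then builds
#' region phases: every region carries the common 0.01-0.1 Hz carrier plus
#' its own mean-reverting (AR(1)) deviation; community members of the active
#' state phase-shift to anti-phase with the carrier (plus Gaussian jitter),
#' forming the planted minority community. The observed signal is
#' `cos(phase) + noise`.
#'
#' @param gt a [make_ground_truth()] object.
#' @param group group name (must be present in `gt$occupancy_profile`).
#' @param gender `"F"` or `"M"` (a nuisance label unless a gender effect was
#'   planted in the ground truth).
#' @param n_volumes number of frames (default 150).
#' @param tr repetition time, seconds (default 2).
#' @param seed integer seed.
#' @param subject_id optional id string.
#' @return a list of class `pl_subject` with `series` (regions x frames),
#'   `hidden_labels`, `phase` (the true generating phases, regions x
#'   frames), `group`, `gender`, `tr`, `seed`.
#' @export
simulate_subject <- function(gt, group, gender = c("F", "M"),
                             n_volumes = 150, tr = 2, seed = 1L,
                             subject_id = NULL) {
  stopifnot(inherits(gt, "pl_ground_truth"))
  gender <- match.arg(gender)
  abort_if(!group %in% names(gt$occupancy_profile),
           sprintf("group '%s' has no occupancy profile", group))
  abort_if(n_volumes < 4, "need at least 4 volumes")

  out <- with_seed(seed, {
    z <- sample_states(gt, group, n_volumes, woman = identical(gender, "F"))
    n <- gt$n_regions
    times <- (seq_len(n_volumes) - 1) * tr
    carrier <- 2 * pi * gt$carrier_freq * times

    # background: carrier plus stationary AR(1) phase deviation per region
    rho <- gt$background_rho
    step_sd <- gt$background_sd * sqrt(1 - rho^2)
    delta <- matrix(0, n, n_volumes)
    delta[, 1] <- rnorm(n, sd = gt$background_sd)
    for (t in 2:n_volumes) {
      delta[, t] <- rho * delta[, t - 1] + rnorm(n, sd = step_sd)
    }
    theta <- sweep(delta, 2, carrier, `+`)

    # community members of the active state lock anti-phase to the carrier
    for (t in seq_len(n_volumes)) {
      memb <- gt$communities[[z[t]]]
      jit <- if (gt$jitter_sd > 0) {
        rnorm(length(memb), sd = gt$jitter_sd)
      } else {
        0
      }
      theta[memb, t] <- carrier[t] + pi + jit
    }

    series <- cos(theta)
    if (gt$noise_sd > 0) {
      series <- series + matrix(rnorm(n * n_volumes, sd = gt$noise_sd), n)
    }
    list(series = series, hidden = z, phase = theta)
  })

  structure(
    list(subject_id = subject_id %||% sprintf("sub-%08d", as.integer(seed)),
         series = out$series, hidden_labels = out$hidden,
         phase = out$phase,
         group = group, gender = gender, tr = tr, seed = as.integer(seed)),
    class = "pl_subject"
  )
}

#' Simulate a two-group cohort
#'
#' Generates `n_low + n_high` subjects with deterministic per-subject seeds
#' derived from `base_seed`, gender assigned per the ground truth's
#' composition (scaled to the requested group sizes).
#'
#' @param gt a [make_ground_truth()] object.
#' @param n_low,n_high subjects per group (defaults 50 and 19).
#' @param n_volumes frames per subject (default 150).
#' @param tr repetition time in seconds (default 2).
#' @param base_seed integer; all subject seeds derive from it.
#' @return a `pl_cohort`: list with `subjects` (tibble: subject_id, group,
#'   gender, tr, seed), `series` (named list of matrices), `hidden_labels`
#'   (named list), `ground_truth`, `tr`, `n_volumes`.
#' @examples
#' gt <- make_ground_truth(n_regions = 20, k_true = 2,
#'   occupancy_by_group = list(low = c(0.5, 0.5), high = c(0.7, 0.3)),
#'   community_sizes = c(5, 5), seed = 1)
#' co <- simulate_cohort(gt, n_low = 2, n_high = 2, n_volumes = 20,
#'                       base_seed = 1)
#' co$subjects
#' @export
simulate_cohort <- function(gt, n_low = 50, n_high = 19, n_volumes = 150,
                            tr = 2, base_seed = 1L) {
  stopifnot(inherits(gt, "pl_ground_truth"))
  groups <- c(rep("low", n_low), rep("high", n_high))
  abort_if(!all(unique(groups) %in% names(gt$occupancy_profile)),
           "ground truth lacks an occupancy profile for a requested group")

  genders <- unlist(lapply(unique(groups), function(g) {
    n_g <- sum(groups == g)
    comp <- gt$gender_composition[[g]] %||% c(1, 1)
    n_f <- round(n_g * comp[1] / sum(comp))
    c(rep("F", n_f), rep("M", n_g - n_f))
  }))

  n <- length(groups)
  seeds <- derive_seeds(base_seed, n)
  ids <- sprintf("sub-%03d", seq_len(n))
  subs <- purrr::pmap(
    list(ids, groups, genders, seeds),
    function(id, g, sex, s) {
      simulate_subject(gt, group = g, gender = sex, n_volumes = n_volumes,
                       tr = tr, seed = s, subject_id = id)
    }
  )
  structure(
    list(
      subjects = tibble::tibble(
        subject_id = ids, group = groups, gender = genders,
        tr = tr, seed = seeds
      ),
      series = setNames(purrr::map(subs, "series"), ids),
      hidden_labels = setNames(purrr::map(subs, "hidden_labels"), ids),
      ground_truth = gt, tr = tr, n_volumes = as.integer(n_volumes)
    ),
    class = "pl_cohort"
  )
}

#' @export
print.pl_cohort <- function(x, ...) {
  cat(sprintf("<pl_cohort> %d subjects (%s), %d regions x %d volumes, TR = %g s\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(table(x$subjects$group)),
                            as.integer(table(x$subjects$group))),
                    collapse = ", "),
              nrow(x$series[[1]]), x$n_volumes, x$tr))
  invisible(x)
}

#' Write a cohort to a directory of delimited text files
#'
#' One whitespace-delimited matrix per subject (regions in rows, no header),
#' a `subjects.tsv` metadata table and, when the cohort is synthetic, a
#' `ground_truth.json` with the planted structure.
#'
#' @param cohort a `pl_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.txt", cohort$subjects$subject_id)
  for (i in seq_along(cohort$series)) {
    utils::write.table(cohort$series[[i]], file.path(dir, files[i]),
                       row.names = FALSE, col.names = FALSE)
  }
  meta <- dplyr::mutate(cohort$subjects, file = files)
  readr::write_tsv(meta, file.path(dir, "subjects.tsv"))
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(n_regions = gt$n_regions, k_true = gt$k_true,
           communities = gt$communities,
           occupancy_profile = gt$occupancy_profile,
           dwell_mean = gt$dwell_mean, carrier_freq = gt$carrier_freq,
           jitter_sd = gt$jitter_sd, noise_sd = gt$noise_sd,
           background_sd = gt$background_sd,
           background_rho = gt$background_rho, seed = gt$seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Also accepts user-supplied data laid out the same way: a `subjects.tsv`
#' with columns `subject_id`, `group`, `gender`, `tr`, `file`, plus one
#' delimited region-by-time matrix per subject (no header).
#'
#' @param dir directory containing `subjects.tsv` and the series files.
#' @return a `pl_cohort` (without ground truth or hidden labels).
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "subjects.tsv"),
                          show_col_types = FALSE)
  abort_if(!all(c("subject_id", "group", "gender", "tr", "file") %in%
                  names(meta)),
           "subjects.tsv must have subject_id, group, gender, tr, file")
  series <- lapply(meta$file, function(f) {
    as.matrix(utils::read.table(file.path(dir, f)))
  })
  series <- lapply(series, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(series) <- meta$subject_id
  tr <- unique(meta$tr)
  abort_if(length(tr) != 1, "all subjects must share one TR")
  structure(
    list(subjects = meta[, c("subject_id", "group", "gender", "tr", "seed")
                         [c("subject_id", "group", "gender", "tr", "seed") %in%
                             names(meta)]],
         series = series, hidden_labels = NULL, ground_truth = NULL,
         tr = tr, n_volumes = ncol(series[[1]])),
    class = "pl_cohort"
  )
}
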