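# Per-frame phase-locking matrices and their leading eigenvectors.
#
# The PL matrix at frame t has entries cos(theta_n - theta_p), which by the
# angle-difference identity equals C C' + S S' with C = cos(theta_t),
# S = sin(theta_t): it has rank at most 2 and its eigenvectors lie in
# span{C, S}. The fast per-frame path below solves the 2x2 projected
# eigenproblem instead of an N x N one; the dense solver is kept as the
# reference route in leading_eigenvector() and in the test suite.

#' Phase-locking matrix of one frame
#'
#' @param theta_t numeric vector of instantaneous phases (radians), one per
#'   region.
#' @return an N x N symmetric matrix with entries `cos(theta_n - theta_p)`,
#'   unit diagonal, values in \[-1, 1\].
#' @examples
#' phase_locking_matrix(c(0, 0, pi / 2))
#' @export
phase_locking_matrix <- function(theta_t) {
  abort_if(!is.numeric(theta_t) || anyNA(theta_t) || !all(is.finite(theta_t)),
           "`theta_t` must be a finite numeric vector")
  cth <- cos(theta_t)
  sth <- sin(theta_t)
  pl <- tcrossprod(cth) + tcrossprod(sth)
  # exact unit diagonal (cos^2 + sin^2 rounds off)
  diag(pl) <- 1
  pl
}

# sign convention: the majority of elements negative; ties broken by making
# the largest-magnitude element negative. Idempotent and invariant to the
# sign of the input.
apply_sign_convention <- function(v) {
  n_neg <- sum(v < 0)
  n_pos <- sum(v > 0)
  flip <- if (n_pos > n_neg) {
    TRUE
  } else if (n_pos == n_neg) {
    v[which.max(abs(v))] > 0
  } else {
    FALSE
  }
  if (flip) -v else v
}

#' Leading eigenvector of a phase-locking matrix
#'
#' Returns the unit-norm eigenvector associated with the largest-magnitude
#' eigenvalue, sign-flipped so that most elements are negative (V and -V
#' represent the same eigenvector; only relative signs between regions carry
#' information). Element signs split the regions into two phase communities;
#' magnitudes measure the strength of membership.
#'
#' @param pl an N x N symmetric phase-locking matrix.
#' @return a list with `v` (unit N-vector) and `eigenvalue`.
#' @examples
#' leading_eigenvector(phase_locking_matrix(c(0, 0, pi)))
#' @export
leading_eigenvector <- function(pl) {
  abort_if(!is.matrix(pl) || nrow(pl) != ncol(pl),
           "`pl` must be a square matrix")
  e <- eigen(pl, symmetric = TRUE)
  i <- which.max(abs(e$values))
  v <- e$vectors[, i]
  v <- v / sqrt(sum(v^2))
  list(v = apply_sign_convention(v), eigenvalue = e$values[i])
}

#' Leading eigenvectors of every frame of a phase array
#'
#' Fast path exploiting the rank-2 structure of phase-locking matrices: for
#' each frame the eigenproblem is projected onto span{cos(theta), sin(theta)}
#' and solved in closed form, avoiding construction of the N x N matrix.
#'
#' @param theta regions x frames matrix of phases (radians).
#' @return a list with `v` (frames x N matrix, one sign-conventioned unit
#'   eigenvector per row) and `eigenvalue` (length-frames vector).
#' @export
leading_eigenvectors <- function(theta) {
  abort_if(!is.matrix(theta) || anyNA(theta) || !all(is.finite(theta)),
           "`theta` must be a finite numeric matrix")
  C <- cos(theta)                      # N x T
  S <- sin(theta)
  aa <- colSums(C * C)
  ab <- colSums(C * S)
  bb <- colSums(S * S)
  # larger eigenvalue of [[aa, ab], [ab, bb]] (both are non-negative, so it
  # is also the largest in magnitude)
  disc <- sqrt((aa - bb)^2 + 4 * ab^2)
  lam <- (aa + bb + disc) / 2
  # eigenvector coordinates in the {C, S} basis; pick the numerically
  # stabler of the two equivalent expressions per frame
  w1a <- ab
  w2a <- lam - aa
  w1b <- lam - bb
  w2b <- ab
  use_b <- (w1a^2 + w2a^2) < (w1b^2 + w2b^2)
  w1 <- ifelse(use_b, w1b, w1a)
  w2 <- ifelse(use_b, w2b, w2a)
  # degenerate frames (ab = 0 and lam = aa or bb): fall back to basis axes
  zero <- (w1^2 + w2^2) == 0
  if (any(zero)) {
    w1[zero] <- as.numeric(aa[zero] >= bb[zero])
    w2[zero] <- as.numeric(aa[zero] < bb[zero])
  }
  V <- t(C) * w1 + t(S) * w2           # T x N
  V <- V / sqrt(rowSums(V^2))
  V <- t(apply(V, 1, apply_sign_convention))
  list(v = V, eigenvalue = lam)
}

#' Pool leading eigenvectors over a cohort
#'
#' Computes the per-frame leading eigenvectors of every subject's phase array
#' and stacks them in subject order, then frame order: with 69 subjects and
#' 148 retained frames each, the pool has 10,212 rows.
#'
#' @param phases a `pl_phases` object from [compute_phases()], or a named
#'   list of regions x frames phase matrices.
#' @param subjects optional subjects tibble (taken from `phases` when it is a
#'   `pl_phases`).
#' @return a `pl_pool`: list with `vectors` (rows x N matrix), `index`
#'   (tibble: subject_id, frame), `eigenvalue`, `n_regions`, `tr`.
#' @export
build_pool <- function(phases, subjects = NULL) {
  if (inherits(phases, "pl_phases")) {
    subjects <- phases$subjects
    tr <- phases$tr
    theta_list <- phases$theta
  } else {
    theta_list <- phases
    tr <- attr(phases, "tr") %||% NA_real_
  }
  abort_if(length(theta_list) == 0, "empty input: no phase arrays")
  n_regions <- unique(vapply(theta_list, nrow, integer(1)))
  abort_if(length(n_regions) != 1,
           "all subjects must share the same number of regions")
  res <- purrr::map(theta_list, leading_eigenvectors)
  vectors <- do.call(rbind, purrr::map(res, "v"))
  index <- purrr::imap_dfr(theta_list, function(th, id) {
    tibble::tibble(subject_id = id, frame = seq_len(ncol(th)))
  })
  structure(
    list(vectors = vectors, index = index,
         eigenvalue = unlist(purrr::map(res, "eigenvalue"), use.names = FALSE),
         n_regions = n_regions, tr = tr),
    class = "pl_pool"
  )
}

#' @export
print.pl_pool <- function(x, ...) {
  cat(sprintf("<pl_pool> %d leading eigenvectors (%d subjects x frames), N = %d\n",
              nrow(x$vectors), length(unique(x$index$subject_id)),
              x$n_regions))
  invisible(x)
}
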