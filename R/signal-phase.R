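# Band-pass filtering and instantaneous phase estimation.
#
# The filter is a Butterworth band-pass designed directly as second-order
# sections (analog prototype poles -> band-pass transform -> bilinear
# transform, conjugate poles paired into biquads). A direct-form transfer
# function of this order is numerically fragile at the very low normalized
# frequencies typical of BOLD data, so the cascade form is used throughout.

# ---- filter design -----------------------------------------------------

# Second-order sections of an order-`order` Butterworth band-pass
# (2*order poles). Returns a matrix with columns b0 b1 b2 a1 a2 (a0 = 1).
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  abort_if(low_hz <= 0 || high_hz <= low_hz,
           "need 0 < low_hz < high_hz")
  abort_if(high_hz >= fs / 2,
           sprintf(paste0("high cutoff (%.4g Hz) must be below the Nyquist ",
                          "frequency (%.4g Hz); check the sampling interval"),
                   high_hz, fs / 2))
  # pre-warped analog band edges (bilinear transform with c = 1)
  wa <- tan(pi * c(low_hz, high_hz) / fs)
  w0 <- sqrt(wa[1] * wa[2])
  bw <- wa[2] - wa[1]

  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # prototype poles
  half <- p_lp * bw / 2
  disc <- sqrt(half^2 - w0^2 + 0i)
  p_bp <- c(half + disc, half - disc)                      # 2*order poles
  z <- (1 + p_bp) / (1 - p_bp)                             # bilinear map

  tol <- 1e-9
  cplx <- z[Im(z) > tol]
  real <- sort(Re(z[abs(Im(z)) <= tol]))
  abort_if(length(cplx) * 2 + length(real) != 2 * order,
           "internal error: pole pairing failed")
  abort_if(length(real) %% 2 != 0, "internal error: unpaired real pole")

  a <- matrix(0, nrow = 0, ncol = 2)
  for (p in cplx) a <- rbind(a, c(-2 * Re(p), Mod(p)^2))
  if (length(real) > 0) {
    for (i in seq(1, length(real), by = 2)) {
      r <- real[i:(i + 1)]
      a <- rbind(a, c(-sum(r), prod(r)))
    }
  }
  # every section carries one zero at z = 1 and one at z = -1
  wc <- 2 * atan(w0)                      # digital center frequency (rad)
  zc <- exp(1i * wc)
  sos <- matrix(0, nrow = nrow(a), ncol = 5)
  for (j in seq_len(nrow(a))) {
    gain <- Mod((1 - zc^-2) / (1 + a[j, 1] * zc^-1 + a[j, 2] * zc^-2))
    sos[j, ] <- c(1 / gain, 0, -1 / gain, a[j, 1], a[j, 2])
  }
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  sos
}

# apply one biquad to the columns of `x` (time in rows)
biquad_filter <- function(x, sec) {
  n <- nrow(x)
  zeros <- matrix(0, 1, ncol(x))
  x1 <- rbind(zeros, x[-n, , drop = FALSE])
  x2 <- rbind(zeros, zeros, x[seq_len(max(n - 2, 0)), , drop = FALSE])
  u <- sec[1] * x + sec[2] * x1 + sec[3] * x2
  y <- stats::filter(u, filter = -sec[4:5], method = "recursive")
  matrix(as.numeric(y), nrow = n)
}

sos_filter <- function(x, sos) {
  for (j in seq_len(nrow(sos))) x <- biquad_filter(x, sos[j, ])
  x
}

# zero-phase (forward-backward) cascade with odd-reflection padding
sos_filtfilt <- function(x, sos, padlen = NULL) {
  n <- nrow(x)
  padlen <- padlen %||% min(n - 1, 150L)
  if (padlen > 0) {
    top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[(padlen + 1):2, , drop = FALSE]
    bot <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
      x[(n - 1):(n - padlen), , drop = FALSE]
    xe <- rbind(top, x, bot)
  } else {
    xe <- x
  }
  y <- sos_filter(xe, sos)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- sos_filter(y, sos)
  y <- y[nrow(y):1, , drop = FALSE]
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  y
}

# ---- user-facing operations -------------------------------------------

#' Band-pass filter a region-by-time signal matrix
#'
#' Filters every region's time course independently with an order-`order`
#' Butterworth band-pass implemented as a cascade of second-order sections.
#' By default the filter is applied forward and backward (zero phase), so no
#' frequency-dependent phase lag is introduced into the signals whose
#' instantaneous phases drive the rest of the analysis; `causal = TRUE`
#' restores a single forward pass for sensitivity analyses.
#'
#' @param series numeric matrix, regions in rows, frames in columns.
#' @param tr repetition time in seconds (sampling interval).
#' @param low_hz,high_hz pass-band edges in Hz. The defaults retain the
#'   0.01-0.1 Hz band conventionally used for resting-state BOLD.
#' @param order Butterworth order (number of analog prototype poles).
#' @param causal if `TRUE`, single forward pass instead of zero-phase.
#' @return a matrix of the same shape as `series`.
#' @examples
#' x <- matrix(rnorm(2 * 200), 2, 200)
#' y <- bandpass(x, tr = 2)
#' dim(y)
#' @export
bandpass <- function(series, tr, low_hz = 0.01, high_hz = 0.1, order = 9,
                     causal = FALSE) {
  check_series(series)
  abort_if(!is.numeric(tr) || tr <= 0, "`tr` must be a positive number")
  sos <- butter_bandpass_sos(order, low_hz, high_hz, fs = 1 / tr)
  x <- t(series)
  y <- if (causal) sos_filter(x, sos) else sos_filtfilt(x, sos)
  out <- t(y)
  dimnames(out) <- dimnames(series)
  out
}

# analytic signal of each column of `x` (time in rows), via the FFT
analytic_signal <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of each region via the analytic signal
#'
#' Each region's (already band-passed) time course is demeaned and Hilbert
#' transformed; the returned phase is the argument of the analytic signal,
#' in (-pi, pi]. The amplitude envelope is returned alongside but plays no
#' further role in the phase-locking analysis.
#'
#' @param series numeric matrix, regions x frames, band-pass filtered.
#' @param demean demean each region before the transform (default `TRUE`).
#' @return a list with elements `theta` (regions x frames matrix of radians)
#'   and `amplitude` (same shape envelope).
#' @examples
#' t <- seq(0, by = 2, length.out = 64)
#' x <- rbind(cos(2 * pi * 0.05 * t), sin(2 * pi * 0.05 * t))
#' ph <- analytic_phase(x)
#' range(ph$theta)
#' @export
analytic_phase <- function(series, demean = TRUE) {
  check_series(series)
  v <- apply(series, 1, stats::var)
  abort_if(any(v == 0),
           paste0("constant (zero-variance) region(s): ",
                  paste(which(v == 0), collapse = ", "),
                  "; phase is undefined"))
  x <- t(series)
  if (demean) x <- sweep(x, 2, colMeans(x))
  a <- analytic_signal(x)
  theta <- Arg(a)
  theta[theta <= -pi] <- pi         # canonical interval (-pi, pi]
  list(theta = t(theta), amplitude = t(Mod(a)))
}

#' Drop boundary frames distorted by the Hilbert transform
#'
#' Removes the first and last `n_trim` frames of a phase (or signal) matrix,
#' where the analytic-signal estimate is least reliable. With the study
#' layout of 150 volumes and `n_trim = 1`, 148 frames are retained.
#'
#' @param theta matrix with frames in columns (regions x frames).
#' @param n_trim frames to drop at each end (default 1).
#' @return the trimmed matrix.
#' @examples
#' ncol(trim_boundary(matrix(0, 3, 150), 1))
#' @export
trim_boundary <- function(theta, n_trim = 1) {
  abort_if(!is.matrix(theta), "`theta` must be a matrix")
  abort_if(n_trim < 0, "`n_trim` must be non-negative")
  if (n_trim == 0) return(theta)
  keep <- ncol(theta) - 2 * n_trim
  abort_if(keep < 1, "trimming would leave no frames")
  theta[, (n_trim + 1):(ncol(theta) - n_trim), drop = FALSE]
}

#' Filter a cohort and estimate per-subject phase arrays
#'
#' Runs [bandpass()], [analytic_phase()] and [trim_boundary()] over every
#' subject of a cohort, returning both the trimmed phase matrices (the input
#' to the dynamic arm) and the filtered series (the input to the static arm).
#'
#' @param cohort a `pl_cohort` (see [simulate_cohort()] or [read_cohort()]).
#' @param low_hz,high_hz,order,causal passed to [bandpass()].
#' @param n_trim frames trimmed at each end after the Hilbert transform.
#' @return a `pl_phases` object: list with `subjects` (tibble), `theta`
#'   (named list of regions x frames phase matrices), `filtered` (named list
#'   of filtered series) and `tr`.
#' @export
compute_phases <- function(cohort, low_hz = 0.01, high_hz = 0.1, order = 9,
                           n_trim = 1, causal = FALSE) {
  stopifnot(inherits(cohort, "pl_cohort"))
  filtered <- purrr::map(cohort$series, bandpass, tr = cohort$tr,
                         low_hz = low_hz, high_hz = high_hz, order = order,
                         causal = causal)
  theta <- purrr::map(filtered, function(s) {
    trim_boundary(analytic_phase(s)$theta, n_trim = n_trim)
  })
  structure(
    list(subjects = cohort$subjects, theta = theta, filtered = filtered,
         tr = cohort$tr, n_trim = n_trim),
    class = "pl_phases"
  )
}

#' @export
print.pl_phases <- function(x, ...) {
  cat(sprintf("<pl_phases> %d subjects, %d regions, %d retained frames, TR = %g s\n",
              length(x$theta), nrow(x$theta[[1]]), ncol(x$theta[[1]]), x$tr))
  invisible(x)
}
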