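# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seeds, kept inside the 32-bit integer range
derive_seeds <- function(base_seed, n) {
  (as.double(base_seed) * 48271 + seq_len(n) * 9973) %% 2147483647
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

is_series_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) >= 2 && ncol(x) >= 4 &&
    all(is.finite(x))
}

check_series <- function(series) {
  abort_if(!is.matrix(series) || !is.numeric(series),
           "`series` must be a numeric region-by-time matrix")
  abort_if(anyNA(series) || !all(is.finite(series)),
           "`series` contains missing or non-finite values")
  abort_if(nrow(series) < 2, "need at least 2 regions")
  abort_if(ncol(series) < 4, "need at least 4 frames")
  invisible(series)
}
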