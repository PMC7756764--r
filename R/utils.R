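#' Derive a reproducible child seed from a parent seed
#'
#' Every stage of the pipeline draws its randomness from a stage seed derived
#' deterministically from one top-level seed, so any stage (a single rotation,
#' a single synthetic session) can be replayed in isolation. The scheme is a
#' simple counter mix: `(seed * 48271 + index) mod (2^31 - 1)`, the classic
#' Lehmer multiplier over the Mersenne prime modulus, which keeps every
#' derived seed a valid positive 32-bit integer and makes distinct
#' `(seed, index)` pairs map to distinct streams in practice.
#'
#' @param seed Integer parent seed.
#' @param index Non-negative integer counter identifying the stage.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.double(seed)) %% m) + 1
  for (i in seq_len(length(index))) {
    s <- (s * 48271 + as.double(index[[i]])) %% m
  }
  as.integer(if (s < 1) 1 else s)
}

# Single binary value vector check used by label-handling functions.
check_binary <- function(x, what = "labels") {
  if (length(x) == 0L) return(invisible(x))
  bad <- !(x %in% c(0, 1))
  if (any(bad)) {
    abort(sprintf(
      "%s must contain only 0 or 1; found value(s) %s",
      what, paste(unique(x[bad])[seq_len(min(3, length(unique(x[bad]))))], collapse = ", ")
    ))
  }
  invisible(x)
}

# dB <-> linear amplitude ratio helpers (20 log10 convention for amplitudes).
db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a) 20 * log10(a)
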